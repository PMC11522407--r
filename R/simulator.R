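#' Simulation setup
#'
#' Describes one synthetic-data condition: clonal structure, expected
#' clones per spot, coverage level (the Gamma shape `r` of the per-cell
#' coverage prior, with rate fixed at 1), spot layout, cell-count noise
#' and missing-mutation masking.
#'
#' @param K number of clones including the mutation-free base clone.
#' @param M number of mutations.
#' @param avg_mut_per_clone target mean number of mutations per clone
#'   (averaged over all K clones).
#' @param expected_clones_per_spot expected number of present clones per
#'   spot, `0 < E < K`.
#' @param coverage_level one of `"very_low"`, `"low"`, `"medium"`,
#'   `"high"`, mapping to `r` of 0.02, 0.07, 0.09, 0.19.
#' @param S number of spots.
#' @param grid_shape spot-array dimensions, `prod(grid_shape) >= S`.
#' @param noise_level cell-count noise added to the true counts before
#'   they are handed to the model: `"none"` (0), `"small"` (Poisson(1)) or
#'   `"large"` (Poisson(10)).
#' @param missing_fraction fraction of mutation rows removed from the
#'   observed data (and genotypes), in `[0, 1)`.
#' @param lambda expected cells per spot used to draw true cell counts.
#' @param f_alpha concentration of the symmetric Dirichlet from which the
#'   true clone prevalences are drawn. The default 10 keeps prevalences
#'   roughly balanced with realistic jitter; see the methods vignette for
#'   the calibration argument.
#' @param l_truth prevalence scaling factor used when drawing the TRUE
#'   per-spot proportions. The default 10 gives Dirichlet concentration of
#'   the order of the number of present clones: genuine spot-to-spot
#'   clonal variability while every present clone keeps non-negligible
#'   mass. The fitted model keeps its standard scaled prior (l = 100).
#'   See the methods vignette for why the truth and the inference prior
#'   use different scales.
#' @param seed optional integer seed.
#' @return An object of class `simulation_setup`.
#' @export
simulation_setup <- function(K = 5, M = 30, avg_mut_per_clone = 13.6,
                             expected_clones_per_spot = 2.5,
                             coverage_level = c("medium", "very_low", "low",
                                                "high"),
                             S = 100, grid_shape = c(10, 10),
                             noise_level = c("none", "small", "large"),
                             missing_fraction = 0, lambda = 25,
                             f_alpha = 10, l_truth = 10, seed = NULL) {
  coverage_level <- match.arg(coverage_level)
  noise_level <- match.arg(noise_level)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)")
  if (expected_clones_per_spot >= K)
    stop("expected clones per spot must be < K")
  if (prod(grid_shape) < S)
    stop("grid_shape too small for S spots")
  structure(
    list(K = K, M = M, avg_mut_per_clone = avg_mut_per_clone,
         expected_clones_per_spot = expected_clones_per_spot,
         coverage_level = coverage_level,
         r = coverage_r_levels()[[coverage_level]],
         S = S, grid_shape = grid_shape, noise_level = noise_level,
         missing_fraction = missing_fraction, lambda = lambda,
         f_alpha = f_alpha, l_truth = l_truth, seed = seed),
    class = "simulation_setup")
}

#' Gamma shapes corresponding to the four coverage levels
#' @return Named numeric vector.
#' @export
coverage_r_levels <- function() {
  c(very_low = 0.02, low = 0.07, medium = 0.09, high = 0.19)
}

#' Simulate clone genotypes on a random evolutionary tree
#'
#' Builds a random rooted tree over K clones (clone 1 is the mutation-free
#' base clone at the root), assigns each mutation to a uniformly chosen
#' non-root branch, and lets every descendant clone inherit it. Trees are
#' re-drawn until the realized mean number of mutations per clone is
#' within 15% of the target; the feasible range is bounded below by `M/K`
#' (every mutation hits at least one clone).
#'
#' @param K number of clones, `>= 2`.
#' @param M number of mutations, `>= 1`.
#' @param avg_mut_per_clone target mean mutations per clone.
#' @param max_tries bound on rejection re-draws.
#' @return List with binary genotype matrix `C` (M x K, column 1 all
#'   zero), `parent` (length-K vector of parent indices, 0 for the root)
#'   and `mut_branch` (branch assignment per mutation).
#' @export
generate_clone_genotypes <- function(K, M, avg_mut_per_clone,
                                     max_tries = 1000) {
  if (K < 2) stop("need at least 2 clones")
  if (M < 1) stop("need at least 1 mutation")
  lo <- avg_mut_per_clone * 0.85
  hi <- avg_mut_per_clone * 1.15
  seen <- c(Inf, -Inf)
  for (try in seq_len(max_tries)) {
    parent <- integer(K)
    for (j in seq(2, K)) parent[j] <- sample.int(j - 1L, 1)
    # descendant closure: anc[k, j] TRUE if clone j is k or below k
    desc <- diag(K) > 0
    for (j in seq(2, K)) {
      anc <- j
      repeat {
        pa <- parent[anc[length(anc)]]
        if (pa == 0) break
        anc <- c(anc, pa)
      }
      desc[anc, j] <- TRUE
    }
    mut_branch <- sample(seq(2, K), M, replace = TRUE)
    C <- matrix(0, M, K)
    for (i in seq_len(M)) C[i, desc[mut_branch[i], ]] <- 1
    mean_mut <- sum(C) / K
    seen <- range(c(seen[is.finite(seen)], mean_mut))
    if (mean_mut >= lo && mean_mut <= hi) {
      rownames(C) <- random_mutation_ids(M)
      colnames(C) <- paste0("clone", seq_len(K))
      return(list(C = C, parent = parent, mut_branch = mut_branch))
    }
  }
  stop("could not reach ", avg_mut_per_clone, " mutations per clone within ",
       "15% after ", max_tries, " tries; achieved range [",
       round(seen[1], 2), ", ", round(seen[2], 2),
       "] (the minimum possible is M/K = ", round(M / K, 2), ")")
}

random_mutation_ids <- function(M) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  paste0("chr", sample(1:22, M, replace = TRUE), ":",
         sample.int(5e7, M), ":", ref, ">", alt)
}

#' Simulate a full dataset with known ground truth
#'
#' Draws clone prevalences from a symmetric Dirichlet, genotypes from
#' [generate_clone_genotypes()], calibrates the Beta shape from the
#' requested expected clones per spot, and runs the generative model
#' forward. Cell-count noise is then added to the true counts to form the
#' prior handed to the model, and optionally a fraction of mutation rows
#' is masked.
#'
#' @param setup a [simulation_setup()].
#' @return List with `data` (a [spot_dataset()] whose `n_prior` carries
#'   the noise), `clones` (a [clone_set()]), `truth` (list `H_true`,
#'   `Z_true`, `N_true`, `Phi_true`, `C_true`, `F_true`), `hyper` (the
#'   generating [hyperparams()]) and `setup`.
#' @export
simulate_dataset <- function(setup) {
  stopifnot(inherits(setup, "simulation_setup"))
  if (!is.null(setup$seed)) set.seed(setup$seed)
  geno <- generate_clone_genotypes(setup$K, setup$M, setup$avg_mut_per_clone)
  F_true <- rgamma(setup$K, setup$f_alpha)
  F_true <- F_true / sum(F_true)
  # the truth is drawn with low Dirichlet concentration (l_truth) so spots
  # differ in clonal makeup; the returned clone set keeps the standard
  # inference-scale prior
  clones_truth <- clone_set(geno$C, F_true, l = setup$l_truth)
  clones <- clone_set(geno$C, F_true)
  zeta <- setup$K *
    zeta_over_K_from_expected_clones(setup$expected_clones_per_spot, setup$K)
  hyper <- hyperparams(zeta = zeta, r = setup$r, p = 1,
                       lambda = setup$lambda)
  coords <- as.matrix(expand.grid(x = seq_len(setup$grid_shape[1]),
                                  y = seq_len(setup$grid_shape[2])))[
                                    seq_len(setup$S), , drop = FALSE]
  draw <- sample_generative(clones_truth, hyper, S = setup$S, coords = coords)
  truth <- list(H_true = draw$state$H, Z_true = draw$state$Z,
                N_true = draw$state$N, Phi_true = draw$state$Phi,
                C_true = clones$C, F_true = F_true)
  n_prior <- add_cell_count_noise(draw$state$N, setup$noise_level)
  data <- spot_dataset(draw$data$A, draw$data$D, coords, n_prior)
  if (setup$missing_fraction > 0) {
    masked <- mask_missing_mutations(data, clones, setup$missing_fraction)
    data <- masked$data
    clones <- masked$clones
    truth$kept_mutations <- masked$kept
  }
  list(data = data, clones = clones, truth = truth, hyper = hyper,
       setup = setup)
}

#' Add noise to per-spot cell counts
#'
#' Additive non-negative noise emulating miscounted nuclei:
#' `none` adds 0, `small` adds Poisson(1) draws and `large` adds
#' Poisson(10) draws, per spot.
#'
#' @param N_true integer vector of true cell counts, all `>= 1`.
#' @param noise_level `"none"`, `"small"` or `"large"`.
#' @return Integer vector of noisy counts (`>= N_true` elementwise).
#' @export
add_cell_count_noise <- function(N_true,
                                 noise_level = c("none", "small", "large")) {
  noise_level <- match.arg(noise_level)
  if (any(N_true < 1)) stop("N_true must be >= 1")
  eps <- switch(noise_level,
                none = 0L,
                small = rpois(length(N_true), 1),
                large = rpois(length(N_true), 10))
  as.integer(N_true + eps)
}

#' Mask a fraction of mutation sites
#'
#' Removes `floor(fraction * M)` uniformly chosen mutation rows from the
#' read-count matrices and the genotype matrix, emulating mutations whose
#' gene regions are never captured by the ST protocol. Clone columns are
#' unchanged.
#'
#' @param data a [spot_dataset()].
#' @param clones a [clone_set()].
#' @param fraction fraction of rows to remove, in `[0, 1)`.
#' @return List with the reduced `data`, `clones`, and `kept` (indices of
#'   retained rows, identical across A, D and C).
#' @export
mask_missing_mutations <- function(data, clones, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  M <- data$M
  n_drop <- floor(fraction * M)
  if (n_drop >= M) stop("masking would remove all mutation rows")
  keep <- sort(sample.int(M, M - n_drop))
  data2 <- spot_dataset(data$A[keep, , drop = FALSE],
                        data$D[keep, , drop = FALSE],
                        data$coords, data$n_prior)
  clones2 <- clone_set(clones$C[keep, , drop = FALSE], clones$F,
                       F0 = clones$F0, l = clones$l)
  list(data = data2, clones = clones2, kept = keep)
}
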