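#' Chain settings for the Gibbs sampler
#'
#' @param n_iter total number of sweeps.
#' @param burn_in number of initial sweeps discarded; must be `< n_iter`.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed optional integer RNG seed; chains with identical seed and
#'   settings are bit-reproducible.
#' @param tune_interval number of sweeps between proposal-scale
#'   adaptations (burn-in only).
#' @param target_accept target acceptance rate per Metropolis block.
#' @param sigma_init initial proposal standard deviations for the Phi, G
#'   and N blocks (length 3, or scalar broadcast).
#' @param store_traces keep full per-sample traces of all latent variables
#'   (intended for small instances and diagnostics).
#' @param phi_init `"data"` (default) initializes every clone's per-cell
#'   coverage at the observed per-site average reads per cell, which puts
#'   the chain at the right coverage scale from the start; `"prior"` draws
#'   the initial values from the Gamma prior.
#' @param warm_start `"nnls"` (default) initializes the clone proportions
#'   of each spot from a weighted non-negative least-squares fit of the
#'   observed variant-allele fractions against the clone genotypes, which
#'   places the chain in the basin supported by the read data; `"prior"`
#'   draws the initial Gamma variables from their prior.
#' @return An object of class `chain_settings`.
#' @export
chain_settings <- function(n_iter = 20000, burn_in = 10000, thin = 5,
                           seed = NULL, tune_interval = 100,
                           target_accept = 0.44,
                           sigma_init = c(phi = 0.5, g = 0.5, n = 0.5),
                           store_traces = FALSE,
                           phi_init = c("data", "prior"),
                           warm_start = c("nnls", "prior")) {
  phi_init <- match.arg(phi_init)
  warm_start <- match.arg(warm_start)
  if (burn_in >= n_iter)
    stop("no post-burn-in samples: burn_in (", burn_in,
         ") must be < n_iter (", n_iter, ")")
  if (burn_in < 0 || thin < 1 || tune_interval < 1)
    stop("burn_in >= 0, thin >= 1 and tune_interval >= 1 required")
  if (target_accept <= 0 || target_accept >= 1)
    stop("target_accept must lie in (0, 1)")
  if (length(sigma_init) == 1) sigma_init <- rep(sigma_init, 3)
  if (length(sigma_init) != 3 || any(sigma_init <= 0))
    stop("sigma_init must be 3 positive values (phi, g, n)")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = seed,
         tune_interval = as.integer(tune_interval),
         target_accept = target_accept,
         sigma_init = as.numeric(sigma_init),
         store_traces = isTRUE(store_traces), phi_init = phi_init,
         warm_start = warm_start),
    class = "chain_settings")
}

#' Adapt a Metropolis proposal scale from its acceptance rate
#'
#' Multiplicative feedback rule applied every `tune_interval` sweeps during
#' burn-in: when the realized acceptance rate exceeds the target the steps
#' are too timid and the scale grows, and vice versa,
#' \deqn{\sigma' = \sigma (1 + (R_c - R_o)).}
#' Adaptation is frozen after burn-in to preserve the stationary
#' distribution.
#'
#' @param sigma current proposal standard deviation (positive).
#' @param target_rate desired acceptance rate `R_o` in (0, 1).
#' @param current_rate realized acceptance rate `R_c` in \[0, 1\].
#' @return Updated proposal standard deviation.
#' @export
adapt_proposal_sigma <- function(sigma, target_rate, current_rate) {
  if (sigma <= 0) stop("sigma must be positive")
  if (target_rate <= 0 || target_rate >= 1) stop("target_rate must be in (0,1)")
  if (current_rate < 0 || current_rate > 1) stop("current_rate must be in [0,1]")
  sigma * (1 + (current_rate - target_rate))
}

#' Run the Metropolis-Hastings-within-Gibbs sampler
#'
#' Iteratively updates all latent variables in the order Pi, Z, Phi, G, N
#' (the cell-count block is skipped when `hyper$fixed_n` is set), with
#' conjugate draws for Pi and Z and zero-truncated-normal random-walk
#' Metropolis steps for Phi, G and N. Proposal scales are tuned towards
#' the target acceptance rate during burn-in and frozen afterwards.
#'
#' @param data a [spot_dataset()].
#' @param clones a [clone_set()]; `clones$M` must equal `data$M`.
#' @param hyper a [hyperparams()].
#' @param settings a [chain_settings()].
#' @return A `posterior_summary`: list with `H_mean` (S x K posterior-mean
#'   clone proportions, rows renormalized to the simplex), `N_mean`,
#'   `Phi_mean`, `Z_mean`, `accept_rates` (per Metropolis block, post
#'   burn-in), `sigma_final`, `loglik_trace` (data log-likelihood at each
#'   kept sample), `kept`, and the full variable traces when
#'   `settings$store_traces` is set.
#' @export
run_chain <- function(data, clones, hyper, settings = chain_settings()) {
  stopifnot(inherits(data, "spot_dataset"), inherits(clones, "clone_set"),
            inherits(hyper, "hyperparams"), inherits(settings, "chain_settings"))
  if (data$M != clones$M)
    stop("dimension mismatch: data has M = ", data$M,
         " mutations but clones have M = ", clones$M)
  S <- data$S; K <- clones$K
  zetaK <- broadcast_spot(hyper$zeta, S, "zeta") / K
  lambda <- broadcast_spot(hyper$lambda, S, "lambda")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  # per-site proposal scales: site coverages span orders of magnitude, so
  # the tuned global scale is modulated by the per-site average reads per
  # cell (floored to keep zero-coverage sites mobile)
  x <- per_cell_read_samples(data$D, data$n_prior)
  phi_scale <- pmax(x, 0.01)
  phi_init <- if (settings$phi_init == "data") pmax(x, 1e-4) else numeric(0)
  g_init <- if (settings$warm_start == "nnls")
    warm_start_g(data, clones) else matrix(0, 0, 0)
  res <- cpp_run_chain(
    A = data$A, D = data$D, C = clones$C,
    gshape1 = g_shapes_present(clones), gshape0 = clones$F0,
    zetaK = zetaK, r = hyper$r, p = hyper$p, lambda = lambda,
    fixed_n = hyper$fixed_n, n_init = data$n_prior,
    n_iter = settings$n_iter, burn_in = settings$burn_in,
    thin = settings$thin, b_adapt = settings$tune_interval,
    r_opt = settings$target_accept, sigma_init = settings$sigma_init,
    phi_scale = phi_scale, phi_init = phi_init, g_init = g_init,
    store_traces = settings$store_traces)
  if (res$kept < 1) stop("no post-burn-in samples")
  H <- res$H_mean / rowSums(res$H_mean)
  dimnames(H) <- list(colnames(data$D), colnames(clones$C))
  dimnames(res$Phi_mean) <- dimnames(clones$C)
  out <- list(H_mean = H, N_mean = as.numeric(res$N_mean),
              Phi_mean = res$Phi_mean, Z_mean = res$Z_mean,
              accept_rates = res$accept_rates,
              sigma_final = res$sigma_final,
              loglik_trace = res$loglik_trace,
              kept = res$kept, settings = settings)
  if (settings$store_traces)
    out[c("trace_H", "trace_G", "trace_Pi", "trace_Phi",
          "trace_N", "trace_Z")] <-
      res[c("trace_H", "trace_G", "trace_Pi", "trace_Phi",
            "trace_N", "trace_Z")]
  structure(out, class = "posterior_summary")
}

# Deterministic moment-based warm start for the proportions: per spot, the
# expected variant-allele fraction is q_i = sum_k C_ik u_k with u the
# expression-weighted proportions, so a D-weighted non-negative least-squares
# fit of A/D on the genotypes points at the data-supported basin. The NNLS
# estimate is shrunk towards the prior-mean proportions with a weight that
# grows with spot read depth, so low-coverage spots start diffuse (a sparse
# start would lock their presence indicators off) while well-covered spots
# start where their reads point.
warm_start_g <- function(data, clones) {
  S <- data$S; K <- clones$K
  shapes <- g_shapes_present(clones)
  total <- sum(shapes)
  fnorm <- shapes / total
  G0 <- matrix(fnorm * total, S, K, byrow = TRUE)
  for (s in seq_len(S)) {
    use <- which(data$D[, s] > 0)
    if (length(use) < 2) next
    w <- sqrt(data$D[use, s])
    X <- clones$C[use, , drop = FALSE] * w
    y <- (data$A[use, s] / data$D[use, s]) * w
    u <- tryCatch(pracma::lsqnonneg(X, y)$x, error = function(e) rep(0, K))
    if (sum(u) <= 0) next
    u <- u / sum(u)
    depth <- sum(data$D[, s])
    wt <- depth / (depth + 20)
    G0[s, ] <- pmax((wt * u + (1 - wt) * fnorm) * total, 0.05)
  }
  G0
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary:", nrow(x$H_mean), "spots x", ncol(x$H_mean),
      "clones;", x$kept, "kept samples\n")
  cat("Acceptance rates (post burn-in): phi =",
      round(x$accept_rates[["phi"]], 3), " g =",
      round(x$accept_rates[["g"]], 3), " n =",
      round(x$accept_rates[["n"]], 3), "\n")
  invisible(x)
}

#' Summarize a list of kept samples
#'
#' Elementwise means over explicitly collected samples; each sample is a
#' list with matrices `H`, `Phi` and vector `N`. Mean proportions are
#' renormalized to the simplex; `N_mean` is reported as a real number.
#'
#' @param kept_samples non-empty list of samples.
#' @return List with `H_mean`, `Phi_mean`, `N_mean`.
#' @export
summarize_posterior <- function(kept_samples) {
  if (length(kept_samples) == 0) stop("no post-burn-in samples")
  n <- length(kept_samples)
  H <- Reduce(`+`, lapply(kept_samples, `[[`, "H")) / n
  list(H_mean = H / rowSums(H),
       Phi_mean = Reduce(`+`, lapply(kept_samples, `[[`, "Phi")) / n,
       N_mean = Reduce(`+`, lapply(kept_samples, `[[`, "N")) / n)
}

#' Single-block conditional updates
#'
#' One full sweep of the named block of the Gibbs sampler, holding all
#' other variables fixed. These expose the exact update kernels used by
#' [run_chain()] for diagnostics and validation on small instances.
#'
#' `gibbs_update_pi` draws each presence probability from its conjugate
#' `Beta(zeta_s/K + Z_sk, 2 - Z_sk)`; `gibbs_update_z` draws each presence
#' indicator proportional to its two unnormalized masses;
#' `mh_update_phi`, `mh_update_g` and `mh_update_n` perform one
#' zero-truncated-normal random-walk Metropolis sweep over the per-cell
#' coverage, the Gamma draws behind the proportions (with `H`
#' re-normalized after every accepted move), and the integer cell counts
#' (unit-interval proposal mass, support `N >= 1`). `mh_update_n` is a
#' no-op when `hyper$fixed_n` is set.
#'
#' @param state a [latent_state()].
#' @param data a [spot_dataset()].
#' @param clones a [clone_set()].
#' @param hyper a [hyperparams()].
#' @param sigma proposal standard deviation for the Metropolis blocks.
#' @return The updated [latent_state()]; the Metropolis updates attach
#'   attributes `accepted` and `proposed` (entry counts for the sweep).
#' @name block_updates
NULL

state_K <- function(state) ncol(state$Z)

#' @rdname block_updates
#' @export
gibbs_update_pi <- function(state, hyper) {
  S <- nrow(state$Z); K <- state_K(state)
  zetaK <- broadcast_spot(hyper$zeta, S, "zeta") / K
  state$Pi <- cpp_gibbs_pi(state$Z, zetaK)
  state
}

#' @rdname block_updates
#' @export
gibbs_update_z <- function(state, clones, hyper) {
  state$Z <- cpp_gibbs_z(state$Pi, state$G, g_shapes_present(clones),
                         clones$F0)
  state
}

#' @rdname block_updates
#' @export
mh_update_phi <- function(state, data, clones, hyper, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  res <- cpp_mh_phi(state$Phi, state$G, clones$C, data$A, data$D, state$N,
                    hyper$r, hyper$p, sigma)
  state$Phi <- res$Phi
  attr(state, "accepted") <- res$accepted
  attr(state, "proposed") <- res$proposed
  state
}

#' @rdname block_updates
#' @export
mh_update_g <- function(state, data, clones, hyper, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  res <- cpp_mh_g(state$G, state$Z, state$Phi, clones$C, data$A, data$D,
                  state$N, g_shapes_present(clones), clones$F0, sigma)
  state$G <- res$G
  state$H <- res$H
  attr(state, "accepted") <- res$accepted
  attr(state, "proposed") <- res$proposed
  state
}

#' @rdname block_updates
#' @export
mh_update_n <- function(state, data, clones, hyper, sigma) {
  if (hyper$fixed_n) {
    attr(state, "accepted") <- 0L
    attr(state, "proposed") <- 0L
    return(state)
  }
  if (sigma <= 0) stop("sigma must be positive")
  S <- length(state$N)
  lambda <- broadcast_spot(hyper$lambda, S, "lambda")
  res <- cpp_mh_n(state$N, state$G, state$Phi, clones$C, data$A, data$D,
                  lambda, sigma)
  state$N <- res$N
  attr(state, "accepted") <- res$accepted
  attr(state, "proposed") <- res$proposed
  state
}
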