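#' Per-mutation average reads per cell
#'
#' Divides each spot's read counts by its estimated cell count and averages
#' over spots, giving one sample per mutation site:
#' \deqn{x_i = \frac{1}{S} \sum_s D_{is} / n_s.}
#' These samples feed the Gamma moment estimator for the per-cell coverage
#' prior.
#'
#' @param D integer matrix, M x S total read counts.
#' @param n length-S estimated cell counts, all `>= 1`.
#' @return Numeric vector of length M.
#' @export
per_cell_read_samples <- function(D, n) {
  D <- as.matrix(D)
  if (ncol(D) == 0) stop("need at least one spot")
  if (length(n) != ncol(D)) stop("n must have one entry per spot")
  if (any(n < 1)) stop("cell counts must be >= 1")
  rowMeans(sweep(D, 2, n, "/"))
}

#' Mixed-type log-moment estimator of Gamma shape and rate
#'
#' \deqn{\hat r = \frac{I \sum_i x_i}{I \sum_i x_i \ln x_i -
#'   \sum_i \ln x_i \sum_i x_i}, \qquad
#'   \hat p = \frac{I^2}{I \sum_i x_i \ln x_i - \sum_i \ln x_i \sum_i x_i}.}
#' Zero entries (sites never observed, for which `ln x` is undefined) are
#' dropped with a message by default, or raise an error.
#'
#' @param x numeric vector of positive samples; at least 2 after zero
#'   handling.
#' @param zero_policy `"drop"` (default) removes non-positive entries with
#'   a message; `"error"` refuses them.
#' @return List with elements `r`, `p`, and `n_dropped`.
#' @export
estimate_gamma_shape_rate <- function(x, zero_policy = c("drop", "error")) {
  zero_policy <- match.arg(zero_policy)
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    if (zero_policy == "error")
      stop(sum(bad), " non-positive sample(s); the log-moment estimator ",
           "requires x > 0")
    message("dropping ", sum(bad), " non-positive sample(s)")
    x <- x[!bad]
  }
  I <- length(x)
  if (I < 2) stop("need at least 2 positive samples")
  denom <- I * sum(x * log(x)) - sum(log(x)) * sum(x)
  if (denom <= 0)
    stop("degenerate log-moment denominator (constant or near-constant ",
         "sample); cannot estimate Gamma parameters")
  list(r = I * sum(x) / denom, p = I^2 / denom, n_dropped = sum(bad))
}

#' Build model hyperparameters from data characteristics
#'
#' Combines the three data-driven estimates: per-spot expected cell counts
#' taken directly from image-derived counts, the Gamma prior on per-cell
#' coverage from the log-moment estimator on per-mutation read averages,
#' and the Beta shape from a user-chosen expected number of clones per
#' spot.
#'
#' @param cell_counts length-S estimated cell counts per spot.
#' @param D M x S total read-count matrix.
#' @param expected_clones target expected number of clones per spot,
#'   `0 < expected_clones < K`.
#' @param K number of clones.
#' @param fixed_n passed through to [hyperparams()].
#' @return A [hyperparams()] object.
#' @export
build_hyperparams <- function(cell_counts, D, expected_clones, K,
                              fixed_n = FALSE) {
  if (length(cell_counts) != ncol(D))
    stop("cell_counts must have one entry per spot (column of D)")
  est <- estimate_gamma_shape_rate(per_cell_read_samples(D, cell_counts))
  zeta <- K * zeta_over_K_from_expected_clones(expected_clones, K)
  hyperparams(zeta = zeta, r = est$r, p = est$p,
              lambda = as.numeric(cell_counts), fixed_n = fixed_n)
}
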