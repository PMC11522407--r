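# Shared fixtures and independent oracles used across the suite.

# deterministic tiny clone set: 2 mutations, 2 clones (clone 1 = base)
tiny_clones <- function(F0 = 0.01) {
  C <- matrix(c(0, 1,
                0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("chr1:100:A>T", "chr2:200:C>G"),
                              c("clone1", "clone2")))
  clone_set(C, c(0.4, 0.6), F0 = F0)
}

tiny_data <- function(A = matrix(c(1L, 0L), 2, 1),
                      D = matrix(c(2L, 1L), 2, 1)) {
  spot_dataset(A, D, coords = cbind(1, 1), n_prior = 3)
}

tiny_state <- function(seed = 1, S = 1, K = 2, M = 2) {
  set.seed(seed)
  G <- matrix(rgamma(S * K, 2, 1) + 0.1, S, K)
  latent_state(Z = matrix(rbinom(S * K, 1, 0.5), S, K),
               Pi = matrix(runif(S * K, 0.2, 0.8), S, K),
               G = G,
               Phi = matrix(rgamma(M * K, 1, 2) + 1e-4, M, K),
               N = rep(3L, S))
}

# term-by-term log-joint oracle, written independently of the package
# implementation: every density is evaluated entry by entry with explicit
# loops
oracle_log_joint <- function(state, data, clones, hyper) {
  S <- nrow(state$Z); K <- ncol(state$Z); M <- nrow(state$Phi)
  zeta <- if (length(hyper$zeta) == 1) rep(hyper$zeta, S) else hyper$zeta
  lambda <- if (length(hyper$lambda) == 1) rep(hyper$lambda, S) else
    hyper$lambda
  shape1 <- pmax(clones$F_disc, clones$F0)
  lp <- 0
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      lp <- lp + dbeta(state$Pi[s, k], zeta[s] / K, 1, log = TRUE)
      lp <- lp + dbinom(state$Z[s, k], 1, state$Pi[s, k], log = TRUE)
      sh <- if (state$Z[s, k] == 1) shape1[k] else clones$F0
      lp <- lp + dgamma(state$G[s, k], sh, rate = 1, log = TRUE)
    }
    if (!hyper$fixed_n)
      lp <- lp + dpois(state$N[s], lambda[s], log = TRUE) -
        log(1 - dpois(0, lambda[s]))
  }
  for (i in seq_len(M))
    for (k in seq_len(K))
      lp <- lp + dgamma(state$Phi[i, k], hyper$r, rate = hyper$p, log = TRUE)
  H <- state$G / rowSums(state$G)
  for (i in seq_len(M)) {
    for (s in seq_len(S)) {
      den <- sum(H[s, ] * state$Phi[i, ])
      num <- sum(H[s, ] * state$Phi[i, ] * clones$C[i, ])
      mu <- state$N[s] * den
      q <- if (den > 0) num / den else 0
      lp <- lp + dpois(data$D[i, s], mu, log = TRUE) +
        dbinom(data$A[i, s], data$D[i, s], q, log = TRUE)
    }
  }
  lp
}

# small simulated dataset + short fit used by several tests
quick_fit <- function(seed = 11, lev = "medium", S = 49, n_iter = 2500,
                      burn_in = 1000, ...) {
  sim <- simulate_dataset(simulation_setup(coverage_level = lev, S = S,
                                           grid_shape = c(7, 7), seed = seed,
                                           ...))
  fit <- run_chain(sim$data, sim$clones, sim$hyper,
                   chain_settings(n_iter = n_iter, burn_in = burn_in,
                                  thin = 2, seed = seed))
  list(sim = sim, fit = fit)
}
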