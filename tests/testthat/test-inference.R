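# Kernel-level checks against independent oracles (enumeration, closed
# forms, direct sampling), then chain-level contracts.

test_that("presence-probability update matches its conjugate Beta", {
  set.seed(1)
  S <- 2; K <- 1
  hyper <- hyperparams(zeta = 0.25 * K, r = 1, p = 1, lambda = 5)
  n <- 2e4
  draws1 <- draws0 <- numeric(n)
  state <- list(Z = matrix(c(1L, 0L), S, K), Pi = matrix(0.5, S, K),
                G = matrix(1, S, K), H = matrix(1, S, K),
                Phi = matrix(1, 1, K), N = rep(1L, S))
  for (i in seq_len(n)) {
    st <- gibbs_update_pi(state, hyper)
    draws1[i] <- st$Pi[1, 1]   # Z = 1 -> Beta(1.25, 1)
    draws0[i] <- st$Pi[2, 1]   # Z = 0 -> Beta(0.25, 2)
  }
  expect_lt(abs(mean(draws1) - 1.25 / 2.25), 3 * sd(draws1) / sqrt(n))
  expect_lt(abs(mean(draws0) - 0.25 / 2.25), 3 * sd(draws0) / sqrt(n))
  ks1 <- suppressWarnings(
    ks.test(draws1, function(q) pbeta(q, 1.25, 1))$statistic)
  ks0 <- suppressWarnings(
    ks.test(draws0, function(q) pbeta(q, 0.25, 2))$statistic)
  expect_lt(ks1, 0.012)
  expect_lt(ks0, 0.012)
})

test_that("presence-indicator update matches brute-force normalization", {
  clones <- clone_set(matrix(c(0, 1), 1, 2), c(0.3, 0.7), F0 = 0.01)
  hyper <- hyperparams(zeta = 1, r = 1, p = 1, lambda = 5)
  shape1 <- pmax(clones$F_disc, clones$F0)
  g <- 2.3; pi_ <- 0.6; k <- 2
  m1 <- pi_ * dgamma(g, shape1[k], rate = 1)
  m0 <- (1 - pi_) * dgamma(g, clones$F0, rate = 1)
  target <- m1 / (m1 + m0)
  state <- list(Z = matrix(1L, 1, 2), Pi = matrix(pi_, 1, 2),
                G = matrix(g, 1, 2), H = matrix(0.5, 1, 2),
                Phi = matrix(1, 1, 2), N = 1L)
  set.seed(2)
  n <- 2e4
  hits <- 0
  for (i in seq_len(n)) hits <- hits +
      gibbs_update_z(state, clones, hyper)$Z[1, k]
  expect_lt(abs(hits / n - target), 3 * sqrt(target * (1 - target) / n))
  # degenerate presence probabilities force the indicator
  st1 <- state; st1$Pi[] <- 1
  expect_equal(gibbs_update_z(st1, clones, hyper)$Z[1, ], c(1L, 1L))
  st0 <- state; st0$Pi[] <- 0
  expect_equal(gibbs_update_z(st0, clones, hyper)$Z[1, ], c(0L, 0L))
})

test_that("coverage update targets its closed-form conditional", {
  # K = 1, C = 1: Binomial factor is constant, so
  # Phi | D, N ~ Gamma(r + D, p + N)
  r <- 2; p <- 3; Nn <- 5L; Dv <- 7L
  clones <- clone_set(matrix(1, 1, 1), 1, F0 = 0.01)
  data <- spot_dataset(matrix(Dv, 1, 1), matrix(Dv, 1, 1), cbind(1, 1), Nn)
  hyper <- hyperparams(zeta = 1, r = r, p = p, lambda = Nn)
  state <- list(Z = matrix(1L, 1, 1), Pi = matrix(0.5, 1, 1),
                G = matrix(2, 1, 1), H = matrix(1, 1, 1),
                Phi = matrix(0.5, 1, 1), N = Nn)
  set.seed(3)
  n <- 3e4
  keep <- numeric(n)
  for (i in seq_len(n)) {
    state <- mh_update_phi(state, data, clones, hyper, sigma = 0.3)
    keep[i] <- state$Phi[1, 1]
  }
  keep <- keep[-(1:2000)][seq(1, n - 2000, by = 5)]  # thin for the KS test
  expect_true(all(keep >= 0))
  ks <- suppressWarnings(
    ks.test(keep, function(q) pgamma(q, r + Dv, rate = p + Nn))$statistic)
  expect_lt(ks, 0.02)
})

test_that("coverage update recovers its prior without data", {
  # S = 0: the conditional reduces to the Gamma(r, p) prior
  r <- 1.5; p <- 2
  clones <- clone_set(matrix(1, 1, 1), 1)
  data <- list(A = matrix(integer(0), 1, 0), D = matrix(integer(0), 1, 0),
               M = 1L, S = 0L)
  hyper <- hyperparams(zeta = 1, r = r, p = p, lambda = 1)
  state <- list(Z = matrix(1L, 0, 1), Pi = matrix(0.5, 0, 1),
                G = matrix(1, 0, 1), H = matrix(1, 0, 1),
                Phi = matrix(0.5, 1, 1), N = integer(0))
  set.seed(4)
  n <- 1e5
  keep <- numeric(n)
  for (i in seq_len(n)) {
    state <- mh_update_phi(state, data, clones, hyper, sigma = 0.6)
    keep[i] <- state$Phi[1, 1]
  }
  keep <- keep[-(1:5000)]
  expect_lt(abs(mean(keep) - r / p), 3 * sd(keep) / sqrt(1000))
  ks <- suppressWarnings(
    ks.test(keep[seq(1, length(keep), by = 10)],
            function(q) pgamma(q, r, rate = p))$statistic)
  expect_lt(ks, 0.02)
})

test_that("proportion update keeps rows on the simplex and matches the
           no-data Gamma stationary law", {
  clones <- clone_set(matrix(c(0, 1), 1, 2), c(0.35, 0.65))
  shape1 <- pmax(clones$F_disc, clones$F0)
  data <- list(A = matrix(integer(0), 0, 1), D = matrix(integer(0), 0, 1),
               M = 0L, S = 1L)
  hyper <- hyperparams(zeta = 1, r = 1, p = 1, lambda = 5)
  state <- list(Z = matrix(1L, 1, 2), Pi = matrix(0.5, 1, 2),
                G = matrix(c(30, 60), 1, 2), H = matrix(0.5, 1, 2),
                Phi = matrix(numeric(0), 0, 2), N = 5L)
  set.seed(5)
  n <- 1.5e5
  keepG <- matrix(0, n, 2); keepH <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    state <- mh_update_g(state, data, clones, hyper, sigma = 6)
    keepG[i, ] <- state$G[1, ]
    keepH[i, ] <- state$H[1, ]
  }
  expect_equal(rowSums(keepH), rep(1, n), tolerance = 1e-12)
  keepG <- keepG[-(1:5000), ]
  # marginal stationary law of each G is its prior Gamma(F'_k, 1)
  for (k in 1:2) {
    ks <- suppressWarnings(
      ks.test(keepG[seq(1, nrow(keepG), by = 12), k],
              function(q) pgamma(q, shape1[k], rate = 1))$statistic)
    expect_lt(ks, 0.02)
  }
  # long-run mean of H matches the Dirichlet mean
  expect_equal(colMeans(keepH[-(1:5000), ]), shape1 / sum(shape1),
               tolerance = 0.01)
})

test_that("cell-count update is integer, supported on N >= 1, and matches
           the truncated-Poisson stationary law without data", {
  lam <- 3
  clones <- clone_set(matrix(c(0, 1), 1, 2), c(0.5, 0.5))
  data <- list(A = matrix(integer(0), 0, 1), D = matrix(integer(0), 0, 1),
               M = 0L, S = 1L)
  hyper <- hyperparams(zeta = 1, r = 1, p = 1, lambda = lam)
  state <- list(Z = matrix(1L, 1, 2), Pi = matrix(0.5, 1, 2),
                G = matrix(c(30, 60), 1, 2), H = matrix(0.5, 1, 2),
                Phi = matrix(numeric(0), 0, 2), N = 5L)
  set.seed(6)
  n <- 3e4
  keep <- integer(n)
  for (i in seq_len(n)) {
    state <- mh_update_n(state, data, clones, hyper, sigma = 2)
    keep[i] <- state$N[1]
  }
  expect_true(all(keep >= 1L))
  keep <- keep[-(1:5000)]
  truncated_mean <- lam / (1 - exp(-lam))
  expect_lt(abs(mean(keep) - truncated_mean), 3 * sd(keep) / sqrt(500))
  # full pmf comparison against the truncated Poisson
  emp <- tabulate(keep, nbins = 15) / length(keep)
  the <- dpois(1:15, lam) / (1 - dpois(0, lam))
  expect_lt(max(abs(cumsum(emp) - cumsum(the))), 0.02)
})

test_that("fixed-N variant never moves the cell counts", {
  sim <- simulate_dataset(simulation_setup(S = 25, grid_shape = c(5, 5),
                                           seed = 8))
  hyper_f <- hyperparams(zeta = sim$hyper$zeta, r = sim$hyper$r,
                         p = sim$hyper$p, lambda = sim$hyper$lambda,
                         fixed_n = TRUE)
  fit <- run_chain(sim$data, sim$clones, hyper_f,
                   chain_settings(n_iter = 400, burn_in = 100, thin = 1,
                                  seed = 1, store_traces = TRUE))
  expect_true(all(fit$trace_N == rep(sim$data$n_prior,
                                     each = nrow(fit$trace_N))))
  expect_true(is.na(fit$accept_rates[["n"]]))
})

test_that("proposal-scale adaptation follows acceptance-rate feedback", {
  expect_equal(adapt_proposal_sigma(1, 0.44, 0.44), 1)
  expect_equal(adapt_proposal_sigma(2, 0.44, 0.64), 2 * 1.2)
  expect_lt(adapt_proposal_sigma(1, 0.44, 0.24), 1)  # too few acceptances
  expect_error(adapt_proposal_sigma(-1, 0.44, 0.5), "positive")
  # self-tuning on a live chain: post-burn-in block acceptance near target
  qf <- quick_fit(seed = 21, n_iter = 3000, burn_in = 1500)
  for (blk in c("phi", "g", "n"))
    expect_lt(abs(qf$fit$accept_rates[[blk]] - 0.44), 0.1)
})

test_that("chains are reproducible and validate their inputs", {
  sim <- simulate_dataset(simulation_setup(S = 16, grid_shape = c(4, 4),
                                           seed = 9))
  st <- chain_settings(n_iter = 300, burn_in = 100, thin = 2, seed = 5)
  f1 <- run_chain(sim$data, sim$clones, sim$hyper, st)
  f2 <- run_chain(sim$data, sim$clones, sim$hyper, st)
  expect_identical(f1$H_mean, f2$H_mean)
  expect_identical(f1$N_mean, f2$N_mean)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_equal(unname(rowSums(f1$H_mean)), rep(1, 16), tolerance = 1e-12)
  expect_error(chain_settings(n_iter = 100, burn_in = 100),
               "no post-burn-in samples")
  bad_clones <- clone_set(sim$clones$C[-1, ], sim$clones$F)
  expect_error(run_chain(sim$data, bad_clones, sim$hyper, st),
               "dimension mismatch")
})

test_that("explicit sample summaries renormalize and average correctly", {
  mk <- function(h, phi, n) list(H = h, Phi = phi, N = n)
  h1 <- matrix(c(0.2, 0.8), 1); h2 <- matrix(c(0.4, 0.6), 1)
  h3 <- matrix(c(0.6, 0.4), 1)
  sm <- summarize_posterior(list(mk(h1, matrix(1, 1, 2), 2),
                                 mk(h2, matrix(2, 1, 2), 3),
                                 mk(h3, matrix(3, 1, 2), 4)))
  expect_equal(sm$H_mean, matrix(c(0.4, 0.6), 1))
  expect_equal(sm$Phi_mean, matrix(2, 1, 2))
  expect_equal(sm$N_mean, 3)
  cst <- summarize_posterior(list(mk(h1, matrix(1, 1, 2), 2L)))
  expect_equal(cst$H_mean, h1)
  expect_error(summarize_posterior(list()), "no post-burn-in")
})
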