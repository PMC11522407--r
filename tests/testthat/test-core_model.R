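test_that("prevalence discretization rounds up to bin bounds and scales", {
  # direct evaluations of the binning rule
  expect_equal(discretize_prevalence(0.32, 100), 35)
  expect_equal(discretize_prevalence(0.05, 100), 5)
  expect_equal(discretize_prevalence(1.0, 100), 100)
  expect_equal(discretize_prevalence(0, 100), 0)
  # bin upper bounds are fixed points (after undoing the scaling)
  f <- seq(0.05, 1, by = 0.05)
  expect_equal(discretize_prevalence(discretize_prevalence(f, 100) / 100, 100),
               discretize_prevalence(f, 100))
  expect_error(discretize_prevalence(0.5, -1), "positive")
  expect_error(discretize_prevalence(1.2), "\\[0, 1\\]")
})

test_that("Beta-shape calibration reproduces the printed values and inverts", {
  expect_equal(zeta_over_K_from_expected_clones(1, 5), 0.25)
  expect_equal(zeta_over_K_from_expected_clones(2.5, 5), 1)
  expect_equal(zeta_over_K_from_expected_clones(4.5, 5), 9)
  expect_equal(expected_clones_per_spot(5, 5), 2.5)
  expect_equal(expected_clones_per_spot(1.25, 5), 1)
  # zeta -> infinity saturates at K
  expect_equal(expected_clones_per_spot(1e12, 5), 5, tolerance = 1e-6)
  # round trip
  for (E in c(0.5, 1, 2.5, 4.5)) {
    zK <- zeta_over_K_from_expected_clones(E, 5)
    expect_equal(expected_clones_per_spot(5 * zK, 5), E)
  }
  expect_error(zeta_over_K_from_expected_clones(5, 5), "< K")
})

test_that("alternated-read success probability matches the weighted zygosity", {
  expect_equal(alt_read_success_probability(1, 2, 1), 1.0)
  expect_equal(alt_read_success_probability(c(0.5, 0.5), c(2, 2), c(1, 0)), 0.5)
  expect_equal(alt_read_success_probability(c(0.25, 0.75), c(4, 1), c(1, 0.5)),
               1.375 / 1.75)
  # homogeneity of degree 0 in Phi
  set.seed(4)
  for (i in 1:20) {
    H <- rgamma(4, 1); H <- H / sum(H)
    Phi <- rgamma(4, 1) + 1e-6
    C <- runif(4)
    q1 <- alt_read_success_probability(H, Phi, C)
    q2 <- alt_read_success_probability(H, Phi * runif(1, 0.1, 50), C)
    expect_equal(q1, q2)
    expect_gte(q1, 0); expect_lte(q1, 1)
  }
  expect_warning(q0 <- alt_read_success_probability(c(1, 0), c(0, 1), c(1, 1)),
                 "degenerate")
  expect_equal(q0, 0)
})

test_that("joint log-density matches an independent term-by-term oracle", {
  clones <- tiny_clones()
  hyper <- hyperparams(zeta = 2, r = 0.5, p = 1.5, lambda = 4)
  data <- tiny_data()
  for (seed in 1:5) {
    state <- tiny_state(seed)
    expect_equal(log_joint_density(state, data, clones, hyper),
                 oracle_log_joint(state, data, clones, hyper),
                 tolerance = 1e-10)
  }
  # fixed-N variant drops the cell-count prior term
  hyper_f <- hyperparams(zeta = 2, r = 0.5, p = 1.5, lambda = 4,
                         fixed_n = TRUE)
  state <- tiny_state(2)
  expect_equal(log_joint_density(state, data, clones, hyper_f),
               oracle_log_joint(state, data, clones, hyper_f),
               tolerance = 1e-10)
})

test_that("prior-only joint equals the sum of prior terms when no data", {
  clones <- tiny_clones()
  hyper <- hyperparams(zeta = 2, r = 0.5, p = 1.5, lambda = 4)
  state <- tiny_state(3)
  empty <- list(A = matrix(integer(0), 0, 0), D = matrix(integer(0), 0, 0),
                M = 0L, S = 0L)
  got <- log_joint_density(
    list(Z = state$Z, Pi = state$Pi, G = state$G, H = state$H,
         Phi = matrix(numeric(0), 0, 2), N = state$N),
    empty, clones, hyper)
  want <- sum(dbeta(state$Pi, 1, 1, log = TRUE)) +
    sum(dbinom(state$Z, 1, state$Pi, log = TRUE)) +
    sum(dgamma(state$G,
               ifelse(state$Z == 1,
                      matrix(pmax(clones$F_disc, clones$F0), 1, 2), clones$F0),
               rate = 1, log = TRUE)) +
    dpois(state$N, 4, log = TRUE) - log(1 - dpois(0, 4))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("flipping one presence indicator changes the joint by its log-odds", {
  clones <- tiny_clones()
  hyper <- hyperparams(zeta = 2, r = 0.5, p = 1.5, lambda = 4)
  data <- tiny_data()
  state <- tiny_state(5)
  for (k in 1:2) {
    s1 <- s0 <- state
    s1$Z[1, k] <- 1L; s0$Z[1, k] <- 0L
    expect_equal(log_joint_density(s1, data, clones, hyper) -
                   log_joint_density(s0, data, clones, hyper),
                 z_log_odds(state, clones, hyper, 1, k),
                 tolerance = 1e-10)
  }
})

test_that("forward draws are self-consistent and hit calibrated moments", {
  K <- 5
  C <- matrix(rbinom(400 * K, 1, 0.4), 400, K); C[, 1] <- 0
  clones <- clone_set(C, rep(0.2, K))
  # zeta/K = 1 gives 2.5 expected clones per spot
  hyper <- hyperparams(zeta = 5, r = 0.09, p = 1, lambda = 25)
  draw <- sample_generative(clones, hyper, S = 2000, seed = 20)
  expect_true(all(draw$data$A <= draw$data$D))
  expect_equal(rowSums(draw$state$H), rep(1, 2000), tolerance = 1e-10)
  expect_equal(draw$state$H,
               draw$state$G / rowSums(draw$state$G), tolerance = 1e-12)
  mz <- mean(rowSums(draw$state$Z))
  se <- sd(rowSums(draw$state$Z)) / sqrt(2000)
  expect_lt(abs(mz - 2.5), 3 * se + 1e-9)
  expect_true(all(draw$state$N >= 1))
  # E[Phi] = r/p
  mphi <- mean(draw$state$Phi)
  sephi <- sd(draw$state$Phi) / sqrt(length(draw$state$Phi))
  expect_lt(abs(mphi - 0.09), 3 * sephi)
  # bit-reproducibility under a fixed seed
  draw2 <- sample_generative(clones, hyper, S = 100, seed = 33)
  draw3 <- sample_generative(clones, hyper, S = 100, seed = 33)
  expect_identical(draw2$data$D, draw3$data$D)
  expect_identical(draw2$state$G, draw3$state$G)
})

test_that("container validators reject malformed inputs", {
  expect_error(clone_set(matrix(c(0, 1.2), 1, 2), c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(clone_set(matrix(0, 1, 2), c(0.6, 0.5)), "sum to 1")
  expect_error(spot_dataset(matrix(3L, 1, 1), matrix(2L, 1, 1),
                            cbind(1, 1), 1), "0 <= A <= D")
  expect_error(spot_dataset(matrix(0L, 1, 2), matrix(0L, 1, 2),
                            rbind(c(1, 1), c(1, 1)), c(1, 1)), "unique")
  expect_error(hyperparams(-1, 1, 1, 1), "zeta")
  expect_error(latent_state(matrix(2L, 1, 1), matrix(0.5, 1, 1),
                            matrix(1, 1, 1), matrix(1, 1, 1), 1), "binary")
  expect_error(latent_state(matrix(1L, 1, 1), matrix(0.5, 1, 1),
                            matrix(1, 1, 1), matrix(1, 1, 1), 0), ">= 1")
})
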