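test_that("cell probabilities match direct arithmetic and sum to one", {
  p <- cell_probs(study_params())
  expect_equal(round(unname(p), 5), c(0.03348, 0.07728, 0.07166, 0.81758))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # perfect tests concentrate on the diagonal
  perf <- cell_probs(c(pi = 0.37, delta1 = 1 - 1e-12, gamma1 = 1 - 1e-12,
                       delta2 = 1 - 1e-12, gamma2 = 1 - 1e-12))
  expect_equal(unname(perf), c(0.37, 0, 0, 0.63), tolerance = 1e-9)

  # disease-free population: driven by false positives only
  g1 <- 0.938; g2 <- 0.937
  none <- cell_probs(c(pi = 1e-15, delta1 = 0.6, gamma1 = g1,
                       delta2 = 0.5, gamma2 = g2))
  expect_equal(unname(none),
               c((1 - g1) * (1 - g2), (1 - g1) * g2, g1 * (1 - g2), g1 * g2),
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    theta <- model_params(runif(1), runif(1), runif(1), runif(1), runif(1))
    pr <- cell_probs(theta)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0 & pr <= 1))
    # margins equal the single-measure positive probabilities
    expect_equal(pr[["p11"]] + pr[["p10"]],
                 marginal_prob(theta[["pi"]], theta[["delta1"]], theta[["gamma1"]]),
                 tolerance = 1e-12)
    expect_equal(pr[["p11"]] + pr[["p01"]],
                 marginal_prob(theta[["pi"]], theta[["delta2"]], theta[["gamma2"]]),
                 tolerance = 1e-12)
  }
})

test_that("log likelihood is the multinomial kernel with the stated pairing", {
  t <- study_table()
  theta <- study_params()
  p <- cell_probs(theta)
  expect_equal(log_likelihood(t, theta),
               164 * log(p[["p11"]]) + 268 * log(p[["p10"]]) +
                 413 * log(p[["p01"]]) + 3312 * log(p[["p00"]]))
  # single-observation perfect-test limit: log pi
  one <- two_by_two(1, 0, 0, 0)
  ll <- log_likelihood(one, c(pi = 0.3, delta1 = 1 - 1e-14, gamma1 = 1 - 1e-14,
                              delta2 = 1 - 1e-14, gamma2 = 1 - 1e-14))
  expect_equal(ll, log(0.3), tolerance = 1e-10)
  # kernel is linear in the counts
  t10 <- two_by_two(1640, 4130, 2680, 33120)
  expect_equal(log_likelihood(t10, theta), 10 * log_likelihood(t, theta))
})

test_that("a zero-probability cell with observations yields -Inf, not an error", {
  # pi = 0 and perfect specificity make the both-positive cell impossible
  # (raw parameter vector: the boundary is outside model_params on purpose)
  theta <- c(pi = 0, delta1 = 0.9, gamma1 = 1, delta2 = 0.9, gamma2 = 1)
  expect_identical(log_likelihood(two_by_two(5, 1, 1, 10), theta), -Inf)
})

test_that("label swap symmetry: measures are exchangeable with the table transpose", {
  set.seed(21)
  for (i in 1:20) {
    cells <- as.vector(rmultinom(1, 2000, c(0.1, 0.2, 0.15, 0.55)))
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t_swap <- two_by_two(cells[1], cells[3], cells[2], cells[4])  # b <-> c
    theta <- model_params(runif(1), runif(1), runif(1), runif(1), runif(1))
    swapped <- model_params(theta[["pi"]], theta[["delta2"]], theta[["gamma2"]],
                            theta[["delta1"]], theta[["gamma1"]])
    expect_equal(log_likelihood(t, theta), log_likelihood(t_swap, swapped),
                 tolerance = 1e-12)
  }
})

test_that("the two-test model is non-identifiable: mirrored parameters fit identically", {
  # swapping the latent class labels maps (pi, d, g) -> (1-pi, 1-g, 1-d)
  theta <- study_params()
  mirror <- model_params(1 - theta[["pi"]],
                         1 - theta[["gamma1"]], 1 - theta[["delta1"]],
                         1 - theta[["gamma2"]], 1 - theta[["delta2"]])
  expect_equal(cell_probs(theta), cell_probs(mirror), tolerance = 1e-12)
  t <- study_table()
  expect_equal(log_likelihood(t, theta), log_likelihood(t, mirror),
               tolerance = 1e-10)
})

test_that("marginal probability and the Rogan-Gladen correction are inverses", {
  expect_equal(marginal_prob(0.086, 0.629, 0.938), 0.110762, tolerance = 1e-6)
  expect_equal(marginal_prob(0.3, 1, 1), 0.3)
  expect_equal(marginal_prob(0, 0.7, 0.9), 0.1, tolerance = 1e-12)

  expect_equal(round(rogan_gladen(432 / 4157, 0.629, 0.938), 3), 0.074)
  expect_equal(rogan_gladen(0.25, 1, 1), 0.25)
  expect_equal(rogan_gladen(1 - 0.938, 0.629, 0.938), 0)
  expect_error(rogan_gladen(0.2, 0.5, 0.5), class = "latentprev_validation_error")

  set.seed(31)
  for (i in 1:30) {
    pi <- runif(1); d <- runif(1, 0.55, 1); g <- runif(1, 0.55, 1)
    expect_equal(rogan_gladen(marginal_prob(pi, d, g), d, g), pi,
                 tolerance = 1e-10)
  }
})

test_that("log posterior equals brute-force recomputation and honours flat priors", {
  t <- study_table()
  priors <- default_priors()
  set.seed(41)
  for (i in 1:20) {
    theta <- model_params(runif(1, 0.01, 0.3), runif(1, 0.4, 0.9),
                          runif(1, 0.8, 0.99), runif(1, 0.3, 0.8),
                          runif(1, 0.8, 0.99))
    expect_equal(log_posterior(t, theta, priors),
                 brute_force_log_posterior(t, theta, priors),
                 tolerance = 1e-10)
  }
  # flat psychometric priors reduce the posterior to the likelihood (the
  # uniform's log density is zero everywhere on (0,1))
  flat <- list(pi = prior_spec("beta", 0.5, sqrt(1 / 12)),
               delta1 = prior_spec("beta", 0.5, sqrt(1 / 12)),
               gamma1 = prior_spec("beta", 0.5, sqrt(1 / 12)),
               delta2 = prior_spec("beta", 0.5, sqrt(1 / 12)),
               gamma2 = prior_spec("beta", 0.5, sqrt(1 / 12)))
  theta <- study_params()
  expect_equal(log_posterior(t, theta, flat), log_likelihood(t, theta))
  expect_error(log_posterior(t, theta, flat[c("pi", "delta1")]),
               class = "latentprev_validation_error")
})

test_that("with point-mass psychometric priors the posterior mode matches Rogan-Gladen", {
  # simulate a large table, fix the test properties at truth, grid-search pi
  s <- synthetic_scenario(n = 50000, seed = 17)
  t <- simulate_crosstab(s)
  tp <- s$true_params
  priors <- list(delta1 = prior_spec("point_mass", tp[["delta1"]]),
                 gamma1 = prior_spec("point_mass", tp[["gamma1"]]),
                 delta2 = prior_spec("point_mass", tp[["delta2"]]),
                 gamma2 = prior_spec("point_mass", tp[["gamma2"]]))
  pis <- seq(0.001, 0.5, by = 0.0005)
  lp <- sapply(pis, function(pi) {
    theta <- c(pi = pi, delta1 = tp[["delta1"]], gamma1 = tp[["gamma1"]],
               delta2 = tp[["delta2"]], gamma2 = tp[["gamma2"]])
    log_posterior(t, theta, priors)
  })
  pi_hat <- pis[which.max(lp)]
  rg <- rogan_gladen((t$a + t$c) / t$n, tp[["delta1"]], tp[["gamma1"]])
  expect_lt(abs(pi_hat - rg), 0.01)  # grid resolution + Monte Carlo error
})

test_that("single-measure log posterior reduces to the conjugate form for a perfect test", {
  n <- 50; k <- 18
  lp <- single_measure_log_posterior(
    n, k,
    delta_prior = prior_spec("point_mass", 1 - 1e-12),
    gamma_prior = prior_spec("point_mass", 1 - 1e-12))
  pis <- seq(0.05, 0.95, by = 0.05)
  vals <- sapply(pis, function(pi)
    lp(c(pi = pi, delta = 1 - 1e-12, gamma = 1 - 1e-12)))
  expect_equal(vals, k * log(pis) + (n - k) * log(1 - pis), tolerance = 1e-6)
  expect_error(single_measure_log_posterior(10, 11,
                                            prior_spec("point_mass", 0.9),
                                            prior_spec("point_mass", 0.9)),
               class = "latentprev_validation_error")
})
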