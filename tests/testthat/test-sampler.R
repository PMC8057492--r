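test_that("sampler config validates and carries defaults", {
  cfg <- sampler_config()
  expect_equal(cfg$n_chains, 12L)
  expect_equal(cfg$n_warmup, 1000L)
  expect_equal(cfg$n_draws, 1000L)
  expect_error(sampler_config(n_chains = 1), class = "latentprev_validation_error")
  expect_error(sampler_config(n_draws = 0), class = "latentprev_validation_error")
  expect_error(sampler_config(target_accept = 1.2),
               class = "latentprev_validation_error")
})

test_that("identical seeds give bit-identical draws; seeds are chain-stable", {
  lp <- function(th) dbeta(th[["p"]], 4, 6, log = TRUE)
  cfg <- sampler_config(3, 100, 100, seed = 7, thin = 1)
  d1 <- sample_posterior(lp, cfg, init = c(p = 0.4))
  d2 <- sample_posterior(lp, cfg, init = c(p = 0.4))
  expect_identical(d1$draws, d2$draws)
  # adding chains leaves existing chains untouched
  d3 <- sample_posterior(lp, sampler_config(5, 100, 100, seed = 7, thin = 1),
                         init = c(p = 0.4))
  expect_identical(d3$draws[, 1:3, ], d1$draws[, , 1])
  expect_identical(d1$seeds, d3$seeds[1:3])
})

test_that("draw array dimensions, support and acceptance bookkeeping are consistent", {
  lp <- function(th) sum(dbeta(th, 2, 2, log = TRUE))
  cfg <- sampler_config(2, 150, 120, seed = 3, thin = 2)
  d <- sample_posterior(lp, cfg, init = c(u = 0.5, v = 0.5))
  expect_equal(dim(d$draws), c(120, 2, 2))
  expect_true(all(d$draws > 0 & d$draws < 1))
  expect_length(d$accept_rate, 2)
  expect_true(all(d$accept_rate >= 0 & d$accept_rate <= 1))
})

test_that("posterior matches the conjugate beta-binomial closed form", {
  n <- 200; k <- 37
  # perfect test, uniform prior: posterior is Beta(k + 1, n - k + 1)
  lp <- function(th) k * log(th[["pi"]]) + (n - k) * log(1 - th[["pi"]])
  d <- sample_posterior(lp, sampler_config(4, 500, 500, seed = 11, thin = 3),
                        init = c(pi = 0.2))
  s <- posterior_summary(d)
  expect_equal(s$mean, (k + 1) / (n + 2), tolerance = 3 * mcse(d, "pi") / s$mean)
})

test_that("with no data the posterior reproduces the prior", {
  priors <- list(delta = prior_spec("truncated_normal", 0.629, 0.02),
                 gamma = prior_spec("beta", 0.937, 0.015))
  lp <- function(th) prior_logdens(priors$delta, th[["delta"]]) +
    prior_logdens(priors$gamma, th[["gamma"]])
  d <- sample_posterior(lp, sampler_config(4, 600, 600, seed = 13, thin = 3),
                        init = c(delta = 0.6, gamma = 0.9))
  s <- posterior_summary(d)
  for (nm in c("delta", "gamma")) {
    m <- prior_moments(priors[[nm]])
    expect_equal(s$mean[s$parameter == nm], m[["mean"]],
                 tolerance = 3 * mcse(d, nm) / m[["mean"]])
  }
})

test_that("initialization fails cleanly when the density is degenerate everywhere", {
  lp <- function(th) -Inf
  expect_error(sample_posterior(lp, sampler_config(2, 50, 50, seed = 1),
                                init = c(p = 0.5)),
               class = "latentprev_sampling_error")
})

test_that("split R-hat matches a hand-computed value on a fixed small array", {
  m <- matrix(c(1.0, 2.0, 1.5, 2.5, 1.2, 2.2,
                0.9, 1.9, 1.1, 2.1, 1.3, 2.3), ncol = 2)
  d <- fake_draws(m)
  # independent arithmetic: split the 6-draw chains into halves of 3
  halves <- cbind(m[1:3, 1], m[4:6, 1], m[1:3, 2], m[4:6, 2])
  W <- mean(apply(halves, 2, var))
  B <- 3 * var(colMeans(halves))
  expected <- sqrt(((3 - 1) / 3 * W + B / 3) / W)
  expect_equal(gelman_rubin(d, "x"), expected, tolerance = 1e-12)
})

test_that("R-hat separates mixed chains from divergent ones", {
  set.seed(23)
  good <- fake_draws(matrix(rnorm(4000), ncol = 4))
  expect_lt(gelman_rubin(good, "x"), 1.01)
  bad <- fake_draws(cbind(rnorm(1000, 0), rnorm(1000, 5)))
  expect_gt(gelman_rubin(bad, "x"), 1.5)
  expect_warning(g <- gelman_rubin(fake_draws(matrix(1, 10, 2)), "x"),
                 "constant")
  expect_true(is.nan(g))
})

test_that("ESS is near the draw count for iid chains and shrinks for AR(1)", {
  set.seed(29)
  iid <- fake_draws(matrix(rnorm(8000), ncol = 4))
  r <- effective_sample_size(iid, "x")
  expect_equal(r$ratio, 1, tolerance = 0.1)
  expect_lte(r$ess, 8000)

  phi <- 0.9
  ar <- sapply(1:4, function(i) as.vector(
    arima.sim(list(ar = phi), 2000)))
  r_ar <- effective_sample_size(fake_draws(ar), "x")
  target <- (1 - phi) / (1 + phi)
  expect_gt(r_ar$ratio, target / 1.5)
  expect_lt(r_ar$ratio, target * 1.5)
})

test_that("posterior summaries use equally tailed type-7 quantiles", {
  d <- fake_draws(matrix(1:100, ncol = 2))
  s <- posterior_summary(d)
  expect_equal(s$median, 50.5)
  expect_equal(s$ci_low, 1 + 99 * 0.025)   # 3.475
  expect_equal(s$ci_high, 1 + 99 * 0.975)  # 97.525, symmetric with the lower
  expect_true(s$ci_low <= s$median && s$median <= s$ci_high)
  expect_lte(s$ess, 100)
})

test_that("draws flatten to a chain/draw data frame", {
  lp <- function(th) dbeta(th[["p"]], 2, 5, log = TRUE)
  d <- sample_posterior(lp, sampler_config(2, 50, 40, seed = 5, thin = 1),
                        init = c(p = 0.3))
  df <- as.data.frame(d)
  expect_equal(nrow(df), 80)
  expect_named(df, c("chain", "draw", "p"))
  expect_equal(df$p[df$chain == 2], as.vector(d$draws[, 2, "p"]))
})
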