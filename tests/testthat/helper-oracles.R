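# Independent oracles for the MCMC correctness tests. These deliberately
# avoid the package's sampling code path: closed forms where they exist,
# brute-force quadrature otherwise.

# Posterior mean of prevalence in the single-measure model with KNOWN
# sensitivity/specificity and a uniform prevalence prior, by fine 1-D grid
# integration of the binomial likelihood in the apparent prevalence.
oracle_single_measure_pi_mean <- function(n, k, delta, gamma,
                                          n_grid = 20000) {
  pi <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  p <- pi * delta + (1 - pi) * (1 - gamma)
  ll <- k * log(p) + (n - k) * log(1 - p)
  w <- exp(ll - max(ll))
  sum(w * pi) / sum(w)
}

# Posterior mean of every parameter in the full five-parameter model by
# coarse 5-D grid quadrature: the four psychometric parameters on +/- 5
# prior-sd grids, prevalence on a wide uniform grid. Feasible because the
# integrand is a product of a multinomial kernel and four near-Gaussian
# priors.
oracle_5d_pi_mean <- function(t, priors, n_pi = 60, n_psy = 15,
                              pi_range = c(0.005, 0.4)) {
  grid_for <- function(p) {
    lo <- max(1e-4, p$location - 5 * p$scale)
    hi <- min(1 - 1e-4, p$location + 5 * p$scale)
    seq(lo, hi, length.out = n_psy)
  }
  d1 <- grid_for(priors$delta1); g1 <- grid_for(priors$gamma1)
  d2 <- grid_for(priors$delta2); g2 <- grid_for(priors$gamma2)
  pis <- seq(pi_range[1], pi_range[2], length.out = n_pi)
  psy <- expand.grid(d1 = d1, g1 = g1, d2 = d2, g2 = g2)
  lpri <- prior_logdens(priors$delta1, psy$d1) +
    prior_logdens(priors$gamma1, psy$g1) +
    prior_logdens(priors$delta2, psy$d2) +
    prior_logdens(priors$gamma2, psy$g2)
  num <- 0; den <- 0; mx <- -Inf
  # two passes: find max log weight, then accumulate stably
  lw_pi <- matrix(NA_real_, nrow(psy), n_pi)
  for (j in seq_len(n_pi)) {
    pi <- pis[j]
    p11 <- pi * psy$d1 * psy$d2 + (1 - pi) * (1 - psy$g1) * (1 - psy$g2)
    p10 <- pi * psy$d1 * (1 - psy$d2) + (1 - pi) * (1 - psy$g1) * psy$g2
    p01 <- pi * (1 - psy$d1) * psy$d2 + (1 - pi) * psy$g1 * (1 - psy$g2)
    p00 <- pi * (1 - psy$d1) * (1 - psy$d2) + (1 - pi) * psy$g1 * psy$g2
    lw_pi[, j] <- t$a * log(p11) + t$c * log(p10) + t$b * log(p01) +
      t$d * log(p00) + lpri
  }
  mx <- max(lw_pi)
  w <- exp(lw_pi - mx)
  sum(colSums(w) * pis) / sum(w)
}

# Log posterior recomputed by explicit summation, independent of
# log_posterior()'s internals.
brute_force_log_posterior <- function(t, theta, priors) {
  p <- cell_probs(theta)
  counts <- c(t$a, t$c, t$b, t$d)
  probs <- c(p[["p11"]], p[["p10"]], p[["p01"]], p[["p00"]])
  total <- 0
  for (i in 1:4) {
    if (counts[i] > 0) total <- total + counts[i] * log(probs[i])
  }
  for (nm in c("delta1", "gamma1", "delta2", "gamma2"))
    total <- total + prior_logdens(priors[[nm]], theta[[nm]])
  if (!is.null(priors$pi))
    total <- total + prior_logdens(priors$pi, theta[["pi"]])
  total
}
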