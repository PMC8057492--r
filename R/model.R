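#' Parameters of the two-measure latent-class model
#'
#' The five parameters: true prevalence `pi`, sensitivity `delta1` and
#' specificity `gamma1` of measure 1 (administrative), sensitivity `delta2`
#' and specificity `gamma2` of measure 2 (survey). All strictly in (0, 1).
#'
#' @param pi,delta1,gamma1,delta2,gamma2 Proportions strictly in (0, 1).
#' @return Named numeric vector of class `model_params`.
#' @examples
#' model_params(0.086, 0.629, 0.938, 0.553, 0.937)
#' @export
model_params <- function(pi, delta1, gamma1, delta2, gamma2) {
  theta <- c(pi = pi, delta1 = delta1, gamma1 = gamma1,
             delta2 = delta2, gamma2 = gamma2)
  if (anyNA(theta) || any(theta <= 0) || any(theta >= 1))
    stop_validation("all model parameters must lie strictly in (0, 1)")
  structure(theta, class = c("model_params", "numeric"))
}

#' Cell probabilities of the observed 2x2 table
#'
#' Under the latent-class model with conditional independence of the two
#' measures given true status, the probability of each observed response
#' pattern is a mixture over the latent status. With `pi` the prevalence,
#' `delta` the sensitivities and `gamma` the specificities:
#' \deqn{p_{11} = \pi\delta_1\delta_2 + (1-\pi)(1-\gamma_1)(1-\gamma_2)}
#' and analogously for the other three patterns. Pattern `p11` is
#' (measure 1 +, measure 2 +), `p10` is (+, -), `p01` is (-, +), `p00` is
#' (-, -).
#'
#' @param theta A [model_params()] vector (or any named numeric with the
#'   five components).
#' @return Named numeric vector `c(p11, p10, p01, p00)` summing to one.
#' @examples
#' cell_probs(model_params(0.086, 0.629, 0.938, 0.553, 0.937))
#' @export
cell_probs <- function(theta) {
  pi <- theta[["pi"]]
  d1 <- theta[["delta1"]]; g1 <- theta[["gamma1"]]
  d2 <- theta[["delta2"]]; g2 <- theta[["gamma2"]]
  c(p11 = pi * d1 * d2 + (1 - pi) * (1 - g1) * (1 - g2),
    p10 = pi * d1 * (1 - d2) + (1 - pi) * (1 - g1) * g2,
    p01 = pi * (1 - d1) * d2 + (1 - pi) * g1 * (1 - g2),
    p00 = pi * (1 - d1) * (1 - d2) + (1 - pi) * g1 * g2)
}

#' Multinomial log likelihood of a 2x2 cross-classification
#'
#' The multinomial kernel of the four observed cells under [cell_probs()]
#' (the combinatorial constant is omitted). Cell `a` (both positive) pairs
#' with `p11`, `c` (measure-1 only) with `p10`, `b` (measure-2 only) with
#' `p01`, `d` with `p00`. A zero probability with a positive count yields
#' `-Inf`, which is a legal return (samplers reject), not an error.
#'
#' @param t A [two_by_two()] table.
#' @param theta A [model_params()] vector.
#' @return Log-likelihood kernel (scalar, possibly `-Inf`).
#' @export
log_likelihood <- function(t, theta) {
  stopifnot(inherits(t, "two_by_two"))
  p <- cell_probs(theta)
  counts <- c(t$a, t$c, t$b, t$d)           # aligned with p11, p10, p01, p00
  probs <- p[c("p11", "p10", "p01", "p00")]
  if (any(probs <= 0 & counts > 0)) return(-Inf)
  keep <- counts > 0
  sum(counts[keep] * log(probs[keep]))
}

#' Probability of testing positive on a single imperfect measure
#'
#' The apparent prevalence implied by true prevalence and the measure's
#' operating characteristics: `pi * delta + (1 - pi) * (1 - gamma)`.
#'
#' @param pi True prevalence.
#' @param delta Sensitivity.
#' @param gamma Specificity.
#' @return Probability of a positive result.
#' @export
marginal_prob <- function(pi, delta, gamma) {
  pi * delta + (1 - pi) * (1 - gamma)
}

#' Rogan-Gladen corrected prevalence
#'
#' Closed-form inversion of [marginal_prob()]: recovers the true prevalence
#' from an apparent prevalence and known sensitivity/specificity,
#' `(apparent - (1 - gamma)) / (delta + gamma - 1)`, clamped to `[0, 1]`.
#' Serves as the deterministic frequentist oracle for the single-measure
#' Bayesian model.
#'
#' @param apparent Apparent (raw) prevalence.
#' @param delta Sensitivity.
#' @param gamma Specificity.
#' @return Corrected prevalence in `[0, 1]`.
#' @examples
#' rogan_gladen(432 / 4157, 0.629, 0.938)  # about 0.074
#' @export
rogan_gladen <- function(apparent, delta, gamma) {
  if (delta + gamma <= 1)
    stop_validation("non-informative test: need sensitivity + specificity > 1")
  min(1, max(0, (apparent - (1 - gamma)) / (delta + gamma - 1)))
}

#' Log posterior of the two-measure latent-class model
#'
#' [log_likelihood()] plus the prior log densities of the five parameters
#' (truncation constants included). The prevalence prior defaults to
#' uniform on (0, 1) when absent from `priors`; the four psychometric
#' priors are required.
#'
#' @param t A [two_by_two()] table.
#' @param theta A [model_params()] vector.
#' @param priors Named list of [prior_spec()] objects for `delta1`,
#'   `gamma1`, `delta2`, `gamma2` and optionally `pi`.
#' @return Log posterior kernel (scalar, possibly `-Inf`).
#' @export
log_posterior <- function(t, theta, priors) {
  needed <- c("delta1", "gamma1", "delta2", "gamma2")
  missing <- setdiff(needed, names(priors))
  if (length(missing))
    stop_validation("missing prior(s) for: %s", paste(missing, collapse = ", "))
  ll <- log_likelihood(t, theta)
  if (!is.finite(ll)) return(-Inf)
  lp <- ll
  for (nm in needed)
    lp <- lp + prior_logdens(priors[[nm]], theta[[nm]])
  if (!is.null(priors$pi))
    lp <- lp + prior_logdens(priors$pi, theta[["pi"]])
  else if (theta[["pi"]] <= 0 || theta[["pi"]] >= 1)
    lp <- -Inf
  lp
}

#' Log posterior of the single-measure misclassification model
#'
#' For one measure alone the data reduce to `k` positives of `n`; the
#' likelihood is the binomial kernel in [marginal_prob()] and the
#' three-parameter posterior (prevalence, sensitivity, specificity) is
#' proper only through the priors. Returns a function of a named vector
#' `c(pi, delta, gamma)` suitable for [sample_posterior()].
#'
#' @param n Sample size.
#' @param k Number testing positive.
#' @param delta_prior,gamma_prior [prior_spec()] objects for the measure's
#'   sensitivity and specificity.
#' @param pi_prior Optional [prior_spec()] for prevalence (default uniform).
#' @return Function `theta -> log posterior`.
#' @export
single_measure_log_posterior <- function(n, k, delta_prior, gamma_prior,
                                         pi_prior = NULL) {
  if (!is_whole(n) || !is_whole(k) || k < 0 || k > n || n <= 0)
    stop_validation("need integer counts with 0 <= k <= n and n > 0")
  force(delta_prior); force(gamma_prior); force(pi_prior)
  function(theta) {
    pi <- theta[["pi"]]; delta <- theta[["delta"]]; gamma <- theta[["gamma"]]
    if (pi <= 0 || pi >= 1) return(-Inf)
    p <- marginal_prob(pi, delta, gamma)
    if ((p <= 0 && k > 0) || (p >= 1 && k < n)) return(-Inf)
    ll <- 0
    if (k > 0) ll <- ll + k * log(p)
    if (k < n) ll <- ll + (n - k) * log(1 - p)
    lp <- ll + prior_logdens(delta_prior, delta) +
      prior_logdens(gamma_prior, gamma)
    if (!is.null(pi_prior)) lp <- lp + prior_logdens(pi_prior, pi)
    lp
  }
}

# Closure over data + priors for the 5-parameter model, used by the fitting
# front ends.
make_log_posterior <- function(t, priors) {
  force(t); force(priors)
  function(theta) log_posterior(t, theta, priors)
}
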