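# High-level fitting front ends. Parameters with point_mass priors are held
# fixed at their location and excluded from sampling; the fit object records
# them so downstream code (PPC, recovery) can reconstitute full parameter
# vectors.

partition_priors <- function(priors, order) {
  priors <- priors[order]
  fixed_mask <- vapply(priors, function(p) p$family == "point_mass", TRUE)
  list(free = priors[!fixed_mask],
       fixed = vapply(priors[fixed_mask], `[[`, 0, "location"))
}

#' Fit the two-measure latent-class prevalence model
#'
#' Assembles the log posterior of the five-parameter latent-class model from
#' a 2x2 cross-classification and informative priors, and samples it with
#' [sample_posterior()]. Initial values are the prior means, with the
#' prevalence initialised at the Rogan-Gladen correction of the measure-1
#' margin evaluated at the prior means (clamped to (0.01, 0.99)).
#' Parameters given `point_mass` priors are fixed, not sampled.
#'
#' @param t A [two_by_two()] table.
#' @param priors Named list of [prior_spec()] objects (`pi` optional,
#'   default uniform); see [default_priors()].
#' @param config A [sampler_config()].
#' @return Object of class `prevalence_fit`: list with `draws`
#'   (a `posterior_draws`), `summary` (from [posterior_summary()]),
#'   `fixed` (named vector of fixed parameters), `table`, `priors`,
#'   `config`, and `model = "two_measure"`.
#' @examples
#' t <- two_by_two(164, 413, 268, 3312)
#' fit <- fit_prevalence(t, config = sampler_config(2, 200, 200, seed = 1))
#' fit$summary
#' @export
fit_prevalence <- function(t, priors = default_priors(),
                           config = sampler_config()) {
  stopifnot(inherits(t, "two_by_two"))
  if (is.null(priors$pi)) priors$pi <- prior_spec("beta", 0.5, sqrt(1 / 12))
  needed <- c("pi", "delta1", "gamma1", "delta2", "gamma2")
  missing <- setdiff(needed, names(priors))
  if (length(missing))
    stop_validation("missing prior(s) for: %s", paste(missing, collapse = ", "))
  parts <- partition_priors(priors, needed)
  init_all <- vapply(priors[needed], `[[`, 0, "location")
  names(init_all) <- needed
  apparent1 <- (t$a + t$c) / t$n
  d1 <- priors$delta1$location; g1 <- priors$gamma1$location
  init_all[["pi"]] <- if (d1 + g1 > 1) {
    min(0.99, max(0.01, rogan_gladen(apparent1, d1, g1)))
  } else 0.5
  fixed <- parts$fixed
  free_names <- setdiff(needed, names(fixed))
  lp_full <- make_log_posterior(t, priors[needed])
  lp_free <- function(theta_free) {
    lp_full(c(theta_free, fixed)[needed])
  }
  draws <- sample_posterior(lp_free, config, init_all[free_names])
  structure(list(draws = draws, summary = posterior_summary(draws),
                 fixed = fixed, table = t, priors = priors[needed],
                 config = config, model = "two_measure"),
            class = "prevalence_fit")
}

#' Fit the single-measure misclassification model
#'
#' The Bayesian counterpart of the Rogan-Gladen correction: a binomial
#' likelihood for the count positive on one measure, with informative
#' priors on that measure's sensitivity and specificity and (by default) a
#' uniform prior on prevalence. Parameter names in the result are `pi`,
#' `delta`, `gamma`.
#'
#' @param t A [two_by_two()] table, from which the margin of the chosen
#'   measure is taken. Alternatively supply `n` and `k` directly.
#' @param measure `"m1"` (administrative) or `"m2"` (survey).
#' @param priors Named list as in [default_priors()]; the pair for the
#'   chosen measure is used. A list with entries `delta`/`gamma` (and
#'   optionally `pi`) is also accepted.
#' @param config A [sampler_config()].
#' @param n,k Sample size and positive count, if no table is given.
#' @return Object of class `prevalence_fit` with `model = "single_measure"`.
#' @examples
#' t <- two_by_two(164, 413, 268, 3312)
#' fit <- fit_single_measure(t, "m1", config = sampler_config(2, 200, 200))
#' @export
fit_single_measure <- function(t = NULL, measure = c("m1", "m2"),
                               priors = default_priors(),
                               config = sampler_config(),
                               n = NULL, k = NULL) {
  measure <- match.arg(measure)
  if (!is.null(t)) {
    stopifnot(inherits(t, "two_by_two"))
    n <- t$n
    k <- if (measure == "m1") t$a + t$c else t$a + t$b
  }
  if (is.null(n) || is.null(k))
    stop_validation("supply a table or both n and k")
  if (!is.null(priors$delta) && !is.null(priors$gamma)) {
    delta_prior <- priors$delta
    gamma_prior <- priors$gamma
  } else {
    idx <- if (measure == "m1") "1" else "2"
    delta_prior <- priors[[paste0("delta", idx)]]
    gamma_prior <- priors[[paste0("gamma", idx)]]
  }
  if (is.null(delta_prior) || is.null(gamma_prior))
    stop_validation("priors must provide sensitivity and specificity for measure '%s'", measure)
  pi_prior <- priors$pi %||% prior_spec("beta", 0.5, sqrt(1 / 12))
  all_priors <- list(pi = pi_prior, delta = delta_prior, gamma = gamma_prior)
  parts <- partition_priors(all_priors, c("pi", "delta", "gamma"))
  fixed <- parts$fixed
  free_names <- setdiff(c("pi", "delta", "gamma"), names(fixed))
  lp_full <- single_measure_log_posterior(n, k, delta_prior, gamma_prior,
                                          pi_prior)
  init_all <- c(pi = 0.5, delta = delta_prior$location,
                gamma = gamma_prior$location)
  d0 <- delta_prior$location; g0 <- gamma_prior$location
  if (d0 + g0 > 1)
    init_all[["pi"]] <- min(0.99, max(0.01, rogan_gladen(k / n, d0, g0)))
  lp_free <- function(theta_free) {
    lp_full(c(theta_free, fixed)[c("pi", "delta", "gamma")])
  }
  draws <- sample_posterior(lp_free, config, init_all[free_names])
  structure(list(draws = draws, summary = posterior_summary(draws),
                 fixed = fixed, n = n, k = k, measure = measure,
                 priors = all_priors, config = config,
                 model = "single_measure"),
            class = "prevalence_fit")
}

#' @export
print.prevalence_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s latent-class fit (%d chains x %d draws)\n",
              if (x$model == "two_measure") "Two-measure" else "Single-measure",
              x$config$n_chains, x$config$n_draws))
  if (length(x$fixed))
    cat("fixed parameters:",
        paste(sprintf("%s = %.3g", names(x$fixed), x$fixed), collapse = ", "),
        "\n")
  print(format_summary(x$summary, digits))
  invisible(x)
}

format_summary <- function(s, digits) {
  s[-1] <- lapply(s[-1], signif, digits = digits)
  s
}

# Full parameter matrix (draws x 5) for the two-measure model, reinstating
# point-mass-fixed parameters as constant columns.
full_param_draws <- function(fit) {
  stopifnot(inherits(fit, "prevalence_fit"), fit$model == "two_measure")
  pooled <- pooled_draws(fit$draws)
  needed <- c("pi", "delta1", "gamma1", "delta2", "gamma2")
  out <- matrix(NA_real_, nrow(pooled), length(needed),
                dimnames = list(NULL, needed))
  for (nm in needed) {
    out[, nm] <- if (nm %in% colnames(pooled)) pooled[, nm]
                 else fit$fixed[[nm]]
  }
  out
}
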