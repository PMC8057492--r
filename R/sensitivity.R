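# Prior-perturbation sensitivity analysis: refit the model with each
# psychometric prior mean shifted while holding the prior variances fixed,
# and track what happens to the posterior prevalence.

sensitivity_row <- function(parameter, shift, location, fit, status = "ok") {
  if (is.null(fit)) {
    return(data.frame(perturbed_parameter = parameter, shift = shift,
                      prior_location = location, pi_mean = NA_real_,
                      pi_low = NA_real_, pi_high = NA_real_, status = status))
  }
  s <- fit$summary[fit$summary$parameter == "pi", ]
  data.frame(perturbed_parameter = parameter, shift = shift,
             prior_location = location, pi_mean = s$mean,
             pi_low = s$ci_low, pi_high = s$ci_high, status = status)
}

#' Prior-mean perturbation grid
#'
#' Refits the two-measure model once per (parameter, shift) pair, shifting
#' one psychometric prior mean at a time by an absolute (percentage-point)
#' amount while holding the prior variance constant, plus a single shared
#' baseline fit. Each fit uses its own seed derived from the master seed so
#' the grid is reproducible as a whole.
#'
#' @param t A [two_by_two()] table.
#' @param base_priors Named list of [prior_spec()] objects (the unperturbed
#'   priors).
#' @param shifts Signed shifts on the proportion scale (default +/- 0.05).
#'   A zero shift is ignored (the baseline row covers it).
#' @param parameters Which prior means to perturb.
#' @param config A [sampler_config()]; fit `i` of the grid runs with the
#'   `i`-th derived seed.
#' @param relative If `TRUE`, shifts are interpreted as relative
#'   (multiplicative) changes `location * (1 + shift)` instead of absolute.
#' @return Object of class `sensitivity_grid`: data frame with columns
#'   `perturbed_parameter` (`"baseline"` for the unperturbed fit), `shift`,
#'   `prior_location`, `pi_mean`, `pi_low`, `pi_high`, `status`; attributes
#'   `base_priors`, `config`.
#' @examples
#' \donttest{
#' t <- two_by_two(164, 413, 268, 3312)
#' g <- run_prior_grid(t, config = sampler_config(2, 300, 300, seed = 1))
#' }
#' @export
run_prior_grid <- function(t, base_priors = default_priors(),
                           shifts = c(-0.05, 0.05),
                           parameters = c("delta1", "gamma1", "delta2", "gamma2"),
                           config = sampler_config(),
                           relative = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  shifts <- shifts[shifts != 0]
  grid <- expand.grid(parameter = parameters, shift = shifts,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(config$seed, nrow(grid) + 1L)
  fit_with_seed <- function(priors, seed) {
    cfg <- config
    cfg$seed <- seed
    fit_prevalence(t, priors, cfg)
  }
  base_fit <- fit_with_seed(base_priors, config$seed)
  rows <- list(sensitivity_row("baseline", 0,
                               NA_real_, base_fit))
  for (i in seq_len(nrow(grid))) {
    par <- grid$parameter[i]
    sh <- grid$shift[i]
    abs_shift <- if (relative) base_priors[[par]]$location * sh else sh
    row <- tryCatch({
      priors <- base_priors
      priors[[par]] <- perturb_prior(priors[[par]], abs_shift)
      fit <- fit_with_seed(priors, seeds[i + 1L])
      sensitivity_row(par, abs_shift, priors[[par]]$location, fit)
    }, error = function(e) {
      sensitivity_row(par, abs_shift,
                      base_priors[[par]]$location + abs_shift, NULL,
                      status = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "base_priors") <- base_priors
  attr(out, "config") <- config
  class(out) <- c("sensitivity_grid", class(out))
  out
}

#' Sweep the survey-specificity prior mean over absolute values
#'
#' The survey measure's specificity is the one prior the posterior
#' prevalence is genuinely sensitive to: because the condition is rare,
#' even a small change in the false-positive rate 1 - gamma2 reallocates
#' many survey-only positives. This sweep refits the model with the
#' `gamma2` prior mean set to each absolute value in `values` (variance
#' held constant), rather than shifted.
#'
#' @param t A [two_by_two()] table.
#' @param base_priors Named list of [prior_spec()] objects.
#' @param values Absolute prior means for `gamma2` (default 0.88, 0.93,
#'   0.98).
#' @param config A [sampler_config()].
#' @return A `sensitivity_grid` as in [run_prior_grid()], with `shift` the
#'   difference from the base location.
#' @export
specificity_sweep <- function(t, base_priors = default_priors(),
                              values = c(0.88, 0.93, 0.98),
                              config = sampler_config()) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(values <= 0 | values >= 1))
    stop_validation("specificity values must lie strictly in (0, 1)")
  seeds <- derive_seeds(config$seed, length(values))
  base_loc <- base_priors$gamma2$location
  rows <- lapply(seq_along(values), function(i) {
    v <- values[i]
    tryCatch({
      priors <- base_priors
      priors$gamma2 <- prior_spec(priors$gamma2$family, location = v,
                                  scale = priors$gamma2$scale)
      cfg <- config
      cfg$seed <- seeds[i]
      fit <- fit_prevalence(t, priors, cfg)
      sensitivity_row("gamma2", v - base_loc, v, fit)
    }, error = function(e) {
      sensitivity_row("gamma2", v - base_loc, v, NULL,
                      status = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "base_priors") <- base_priors
  attr(out, "config") <- config
  class(out) <- c("sensitivity_grid", class(out))
  out
}

#' Forest-style plot of a sensitivity grid
#'
#' Posterior prevalence mean and 95% interval for each perturbation row.
#'
#' @param grid A [run_prior_grid()] or [specificity_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_validation("plotting requires the ggplot2 package")
  df <- as.data.frame(grid)
  df$label <- ifelse(df$perturbed_parameter == "baseline", "baseline",
                     sprintf("%s %+0.2f", df$perturbed_parameter, df$shift))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi_mean, y = .data$label)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pi_low, xmax = .data$pi_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "posterior prevalence", y = NULL,
                  title = "Prior-perturbation sensitivity")
}
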