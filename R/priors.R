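#' Construct a prior specification for a proportion-valued parameter
#'
#' Priors for the latent-class parameters (prevalence, sensitivities,
#' specificities) are location/scale summaries on the proportion scale,
#' supported on the open interval (0, 1). Three families are available:
#'
#' * `truncated_normal` (default): a normal with the stated mean and
#'   standard deviation, truncated to (0, 1). This is the natural carrier of
#'   an asymptotic sampling distribution from a validation study.
#' * `beta`: moment-matched via [beta_from_moments()].
#' * `point_mass`: a degenerate prior fixing the parameter at `location`
#'   (used for oracle tests and for treating a test property as known).
#'
#' @param family Prior family.
#' @param location Prior mean, strictly in (0, 1).
#' @param scale Standard deviation on the proportion scale (ignored for
#'   `point_mass`).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec("truncated_normal", 0.629, 0.0197)
#' prior_spec("beta", 0.5, sqrt(1 / 12))  # uniform
#' @export
prior_spec <- function(family = c("truncated_normal", "beta", "point_mass"),
                       location, scale = NULL) {
  family <- match.arg(family)
  if (!is.numeric(location) || length(location) != 1L ||
      location <= 0 || location >= 1)
    stop_validation("prior location must lie strictly in (0, 1)")
  shapes <- NULL
  if (family == "point_mass") {
    scale <- 0
  } else {
    if (is.null(scale) || !is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop_validation("prior scale must be a positive number")
    if (family == "beta") shapes <- beta_from_moments(location, scale)
  }
  structure(list(family = family, location = location, scale = scale,
                 shapes = shapes),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: %s(location = %.4g, scale = %.4g)\n",
              x$family, x$location, x$scale))
  invisible(x)
}

#' Build an informative prior from a validation-study summary
#'
#' Uses the asymptotic sampling distribution of the reported statistic: the
#' prior is centred at the validation estimate with standard deviation
#' `sqrt(p (1 - p) / n_effective)`, where `n_effective` is the denominator
#' of the statistic (number of true cases for a sensitivity, true
#' non-cases for a specificity). Validation reports often state only the
#' total validation sample size; in that case the denominator is
#' approximated as `round(case_fraction * n_total)` for a sensitivity and
#' `round((1 - case_fraction) * n_total)` for a specificity.
#'
#' @param estimate Reported proportion (sensitivity or specificity),
#'   strictly in (0, 1).
#' @param n_effective Denominator of the statistic, if known.
#' @param n_total Total validation sample size (used with `case_fraction`
#'   when `n_effective` is unknown).
#' @param statistic `"sensitivity"` or `"specificity"`; determines which
#'   side of `case_fraction` applies when resolving `n_effective`.
#' @param case_fraction Assumed fraction of true cases in the validation
#'   sample (default 0.2).
#' @param family Prior family passed to [prior_spec()].
#' @return A [prior_spec()].
#' @examples
#' prior_from_validation(0.629, n_total = 3362, statistic = "sensitivity")
#' prior_from_validation(0.553, n_effective = 65)
#' @export
prior_from_validation <- function(estimate, n_effective = NULL, n_total = NULL,
                                  statistic = c("sensitivity", "specificity"),
                                  case_fraction = 0.2,
                                  family = "truncated_normal") {
  statistic <- match.arg(statistic)
  if (!is.numeric(estimate) || estimate <= 0 || estimate >= 1)
    stop_validation("validation estimate must lie strictly in (0, 1)")
  if (is.null(n_effective)) {
    if (is.null(n_total))
      stop_validation("supply n_effective, or n_total with case_fraction")
    frac <- if (statistic == "sensitivity") case_fraction else 1 - case_fraction
    n_effective <- round(frac * n_total)
  }
  if (n_effective <= 0)
    stop_validation("effective denominator must be positive")
  prior_spec(family, location = estimate,
             scale = sqrt(estimate * (1 - estimate) / n_effective))
}

#' Match a beta distribution to a mean and standard deviation
#'
#' @param mean Target mean in (0, 1).
#' @param sd Target standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_moments(0.5, sqrt(1 / 12))  # c(1, 1)
#' @export
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop_validation("mean must lie strictly in (0, 1)")
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop_validation("infeasible moments: need sd^2 < mean (1 - mean)")
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Shift a prior mean, holding its spread fixed
#'
#' The perturbation used by the prior-sensitivity analysis: the location
#' moves by `shift` percentage points (on the proportion scale) while the
#' scale -- the prior variance -- is unchanged.
#'
#' @param p A [prior_spec()].
#' @param shift Signed shift on the proportion scale.
#' @return A new [prior_spec()] of the same family.
#' @examples
#' perturb_prior(prior_spec("truncated_normal", 0.937, 0.015), -0.05)
#' @export
perturb_prior <- function(p, shift) {
  stopifnot(inherits(p, "prior_spec"))
  loc <- p$location + shift
  if (loc <= 0 || loc >= 1)
    stop_validation("shifted prior location %.3f outside (0, 1)", loc)
  prior_spec(p$family, location = loc,
             scale = if (p$family == "point_mass") NULL else p$scale)
}

#' Prior log density
#'
#' Log density of a [prior_spec()] at `x`, including the truncation
#' normalising constant for the truncated-normal family so that densities
#' are comparable across families. Returns `-Inf` outside (0, 1). For a
#' `point_mass` prior the convention is 0 at the location and `-Inf`
#' elsewhere (the parameter is normally held fixed rather than sampled).
#'
#' @param p A [prior_spec()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of log densities.
#' @export
prior_logdens <- function(p, x) {
  stopifnot(inherits(p, "prior_spec"))
  out <- rep(-Inf, length(x))
  inside <- x > 0 & x < 1
  if (p$family == "truncated_normal") {
    z <- pnorm(1, p$location, p$scale) - pnorm(0, p$location, p$scale)
    out[inside] <- dnorm(x[inside], p$location, p$scale, log = TRUE) - log(z)
  } else if (p$family == "beta") {
    out[inside] <- dbeta(x[inside], p$shapes[["alpha"]], p$shapes[["beta"]],
                         log = TRUE)
  } else {
    out[x == p$location] <- 0
  }
  out
}

#' Draw samples from a prior
#'
#' Truncated normals are drawn by inverse-CDF sampling restricted to (0, 1);
#' beta priors via `rbeta`; point masses return the location.
#'
#' @param p A [prior_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` in (0, 1).
#' @export
prior_sample <- function(p, n) {
  stopifnot(inherits(p, "prior_spec"))
  switch(p$family,
    truncated_normal = {
      lo <- pnorm(0, p$location, p$scale)
      hi <- pnorm(1, p$location, p$scale)
      qnorm(runif(n, lo, hi), p$location, p$scale)
    },
    beta = rbeta(n, p$shapes[["alpha"]], p$shapes[["beta"]]),
    point_mass = rep(p$location, n))
}

#' Analytic mean and standard deviation of a prior
#'
#' For the truncated-normal family these are the moments after truncation to
#' (0, 1); for priors whose location is far from the boundary they are
#' essentially the location and scale.
#'
#' @param p A [prior_spec()].
#' @return Named numeric vector `c(mean, sd)`.
#' @export
prior_moments <- function(p) {
  stopifnot(inherits(p, "prior_spec"))
  switch(p$family,
    point_mass = c(mean = p$location, sd = 0),
    beta = c(mean = p$location, sd = p$scale),
    truncated_normal = {
      a <- (0 - p$location) / p$scale
      b <- (1 - p$location) / p$scale
      z <- pnorm(b) - pnorm(a)
      m <- p$location + p$scale * (dnorm(a) - dnorm(b)) / z
      v <- p$scale^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                          ((dnorm(a) - dnorm(b)) / z)^2)
      c(mean = m, sd = sqrt(v))
    })
}

#' Default informative priors for the two-measure analysis
#'
#' Priors centred at the published validation estimates for the two
#' measures: administrative sensitivity 62.9% and specificity 93.8%
#' (validation n = 3362), survey sensitivity 55.3% and specificity 93.7%
#' (validation n = 325). Scales come from the asymptotic sampling
#' distribution with the validation denominators resolved through
#' `case_fraction` (see [prior_from_validation()]). The prevalence prior is
#' uniform on (0, 1).
#'
#' @param case_fraction Assumed case fraction in the validation samples.
#' @param family Prior family for the four psychometric parameters.
#' @return Named list of [prior_spec()] objects: `pi`, `delta1`, `gamma1`,
#'   `delta2`, `gamma2` (delta = sensitivity, gamma = specificity;
#'   1 = administrative, 2 = survey).
#' @examples
#' str(default_priors(), max.level = 1)
#' @export
default_priors <- function(case_fraction = 0.2, family = "truncated_normal") {
  list(
    pi = prior_spec("beta", 0.5, sqrt(1 / 12)),  # uniform(0, 1)
    delta1 = prior_from_validation(0.629, n_total = 3362,
                                   statistic = "sensitivity",
                                   case_fraction = case_fraction, family = family),
    gamma1 = prior_from_validation(0.938, n_total = 3362,
                                   statistic = "specificity",
                                   case_fraction = case_fraction, family = family),
    delta2 = prior_from_validation(0.553, n_total = 325,
                                   statistic = "sensitivity",
                                   case_fraction = case_fraction, family = family),
    gamma2 = prior_from_validation(0.937, n_total = 325,
                                   statistic = "specificity",
                                   case_fraction = case_fraction, family = family))
}

#' Read a prior configuration from YAML or JSON
#'
#' Each named entry is either a fully specified prior
#' `{family, location, scale}` or a validation summary
#' `{estimate, n_total (or n_effective), statistic, case_fraction}`.
#' Parameters not listed fall back to [default_priors()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param case_fraction Default case fraction for validation entries.
#' @return Named list of [prior_spec()] objects.
#' @export
read_priors <- function(path, case_fraction = 0.2) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  cfg <- switch(tolower(tools::file_ext(path)),
    yaml = , yml = tryCatch(yaml::read_yaml(path), error = function(e)
      stop_io("failed to parse YAML '%s': %s", path, conditionMessage(e))),
    json = tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop_io("failed to parse JSON '%s': %s", path, conditionMessage(e))),
    stop_io("prior config must be YAML or JSON: %s", path))
  if (!is.list(cfg) || is.null(names(cfg)))
    stop_validation("prior config must be a named mapping of parameters")
  known <- c("pi", "delta1", "gamma1", "delta2", "gamma2", "delta", "gamma")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_validation("unknown prior parameter(s): %s", paste(bad, collapse = ", "))
  priors <- default_priors(case_fraction)
  for (nm in names(cfg)) {
    e <- cfg[[nm]]
    priors[[nm]] <- if (!is.null(e$family) && !is.null(e$location)) {
      prior_spec(e$family, e$location, e$scale)
    } else if (!is.null(e$estimate)) {
      stat <- e$statistic %||%
        (if (grepl("^delta", nm)) "sensitivity" else "specificity")
      prior_from_validation(e$estimate, n_effective = e$n_effective,
                            n_total = e$n_total, statistic = stat,
                            case_fraction = e$case_fraction %||% case_fraction)
    } else {
      stop_validation("prior entry '%s' needs {family, location, scale} or {estimate, ...}", nm)
    }
  }
  priors
}

#' Tidy table of resolved prior specifications
#'
#' @param priors Named list of [prior_spec()] objects.
#' @return Data frame with `parameter`, `family`, `location`, `scale`.
#' @export
priors_table <- function(priors) {
  data.frame(parameter = names(priors),
             family = vapply(priors, `[[`, "", "family"),
             location = vapply(priors, `[[`, 0, "location"),
             scale = vapply(priors, `[[`, 0, "scale"),
             row.names = NULL)
}
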