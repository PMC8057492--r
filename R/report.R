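# File-level entry points behind the command-line wrapper: each reads its
# inputs, delegates to the modelling functions, writes tidy CSV outputs plus
# a JSON run manifest, and returns the output paths.

write_manifest <- function(out_dir, command, inputs, config, seed, outputs) {
  input_hashes <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  manifest <- list(
    command = command,
    package = "latentprev",
    version = as.character(packageVersion("latentprev")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    input_md5 = input_hashes,
    config = config,
    outputs = outputs)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  path
}

config_list <- function(config) {
  unclass(config)
}

resolve_inputs <- function(data, priors_path, case_fraction = 0.2) {
  t <- read_crosstab(data)
  priors <- if (is.null(priors_path)) default_priors(case_fraction)
            else read_priors(priors_path, case_fraction)
  list(table = t, priors = priors)
}

#' Fit the model from files and write summary, draws and manifest
#'
#' Reads a cross-classification (and optionally a prior configuration),
#' fits either the two-measure latent-class model or a single-measure
#' model, and writes `fit_summary.csv` (one row per parameter with
#' mean/median/95% CI/R-hat/ESS), `fit_draws.csv` (chain, draw, parameter
#' columns) and `fit_manifest.json` into `out_dir`. Warns if any R-hat
#' is 1.01 or more, or the smallest ESS ratio falls below 0.1.
#'
#' @param data Path to the cross-classification (see [read_crosstab()]).
#' @param priors Optional path to a prior configuration (see
#'   [read_priors()]); defaults to [default_priors()].
#' @param out_dir Output directory, created if needed.
#' @param seed Master seed.
#' @param chains,warmup,draws Sampler settings.
#' @param single_measure `NULL` for the two-measure model, else `"m1"`
#'   (administrative) or `"m2"` (survey).
#' @param case_fraction Passed to the default prior construction.
#' @return Invisibly, a named list of output paths.
#' @export
run_fit <- function(data, priors = NULL, out_dir = ".", seed = 1,
                    chains = 12, warmup = 1000, draws = 1000,
                    single_measure = NULL, case_fraction = 0.2) {
  inp <- resolve_inputs(data, priors, case_fraction)
  config <- sampler_config(chains, warmup, draws, seed)
  fit <- if (is.null(single_measure)) {
    fit_prevalence(inp$table, inp$priors, config)
  } else {
    fit_single_measure(inp$table, match.arg(single_measure, c("m1", "m2")),
                       inp$priors, config)
  }
  if (any(fit$summary$rhat >= 1.01, na.rm = TRUE))
    warning("R-hat >= 1.01 for: ",
            paste(fit$summary$parameter[fit$summary$rhat >= 1.01], collapse = ", "))
  if (any(fit$summary$ess_ratio < 0.1, na.rm = TRUE))
    warning("ESS ratio < 0.1 for: ",
            paste(fit$summary$parameter[fit$summary$ess_ratio < 0.1], collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "fit_summary.csv")
  draws_path <- file.path(out_dir, "fit_draws.csv")
  write.csv(fit$summary, summary_path, row.names = FALSE)
  write.csv(as.data.frame(fit$draws), draws_path, row.names = FALSE)
  manifest <- write_manifest(out_dir, "fit",
                             list(data = data, priors = priors),
                             config_list(config), seed,
                             list(summary = summary_path, draws = draws_path))
  invisible(list(summary = summary_path, draws = draws_path,
                 manifest = manifest, fit = fit))
}

#' Run a posterior predictive check from files
#'
#' Fits the two-measure model and writes the per-cell predictive summary to
#' `ppc.csv` plus a manifest.
#'
#' @inheritParams run_fit
#' @return Invisibly, a named list of output paths.
#' @export
run_ppc <- function(data, priors = NULL, out_dir = ".", seed = 1,
                    chains = 12, warmup = 1000, draws = 1000,
                    case_fraction = 0.2) {
  inp <- resolve_inputs(data, priors, case_fraction)
  config <- sampler_config(chains, warmup, draws, seed)
  fit <- fit_prevalence(inp$table, inp$priors, config)
  ppc <- ppc_summary(posterior_predictive(fit), inp$table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ppc_path <- file.path(out_dir, "ppc.csv")
  write.csv(as.data.frame(ppc), ppc_path, row.names = FALSE)
  manifest <- write_manifest(out_dir, "ppc",
                             list(data = data, priors = priors),
                             config_list(config), seed,
                             list(ppc = ppc_path))
  invisible(list(ppc = ppc_path, manifest = manifest, result = ppc))
}

#' Run the prior-sensitivity analysis from files
#'
#' Writes the perturbation grid (and, when requested, the
#' survey-specificity sweep) as tidy CSV plus a manifest.
#'
#' @inheritParams run_fit
#' @param shifts Signed prior-mean shifts for the grid.
#' @param sweep Optional numeric vector of absolute survey-specificity
#'   prior means to sweep (e.g. `c(0.88, 0.93, 0.98)`); `NULL` to skip.
#' @return Invisibly, a named list of output paths.
#' @export
run_sensitivity <- function(data, priors = NULL, out_dir = ".", seed = 1,
                            chains = 12, warmup = 1000, draws = 1000,
                            shifts = c(-0.05, 0.05), sweep = NULL,
                            case_fraction = 0.2) {
  inp <- resolve_inputs(data, priors, case_fraction)
  config <- sampler_config(chains, warmup, draws, seed)
  grid <- run_prior_grid(inp$table, inp$priors, shifts = shifts,
                         config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid_path <- file.path(out_dir, "sensitivity_grid.csv")
  write.csv(as.data.frame(grid), grid_path, row.names = FALSE)
  outputs <- list(grid_csv = grid_path)
  if (!is.null(sweep)) {
    sw <- specificity_sweep(inp$table, inp$priors, values = sweep,
                            config = config)
    sweep_path <- file.path(out_dir, "specificity_sweep.csv")
    write.csv(as.data.frame(sw), sweep_path, row.names = FALSE)
    outputs$sweep_csv <- sweep_path
  }
  manifest <- write_manifest(out_dir, "sensitivity",
                             list(data = data, priors = priors),
                             c(config_list(config), list(shifts = shifts, sweep = sweep)),
                             seed, outputs)
  invisible(c(outputs, list(manifest = manifest, result = grid)))
}

#' Simulate a synthetic cross-classification from files or arguments
#'
#' Writes the simulated table as `simulated_crosstab.csv` (header
#' `a,b,c,d`) plus a manifest. The scenario can come from a YAML/JSON file
#' (keys `pi, delta1, gamma1, delta2, gamma2, n`) or from the arguments.
#'
#' @param scenario Optional path to a scenario config.
#' @param out_dir Output directory.
#' @param seed Scenario seed.
#' @param pi,delta1,gamma1,delta2,gamma2 True parameters (used when no
#'   scenario file is given).
#' @param n Sample size.
#' @return Invisibly, a named list of output paths.
#' @export
run_simulate <- function(scenario = NULL, out_dir = ".", seed = 1,
                         pi = 0.086, delta1 = 0.629, gamma1 = 0.938,
                         delta2 = 0.553, gamma2 = 0.937, n = 4157) {
  if (!is.null(scenario)) {
    if (!file.exists(scenario)) stop_io("file not found: %s", scenario)
    cfg <- switch(tolower(tools::file_ext(scenario)),
      yaml = , yml = fix_yaml_n(yaml::read_yaml(scenario)),
      json = jsonlite::read_json(scenario, simplifyVector = TRUE),
      stop_io("scenario config must be YAML or JSON: %s", scenario))
    pi <- cfg$pi %||% pi; n <- cfg$n %||% n
    delta1 <- cfg$delta1 %||% delta1; gamma1 <- cfg$gamma1 %||% gamma1
    delta2 <- cfg$delta2 %||% delta2; gamma2 <- cfg$gamma2 %||% gamma2
  }
  s <- synthetic_scenario(model_params(pi, delta1, gamma1, delta2, gamma2),
                          n = n, seed = seed)
  tab <- simulate_crosstab(s)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(out_dir, "simulated_crosstab.csv")
  write.csv(data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
            tab_path, row.names = FALSE)
  manifest <- write_manifest(out_dir, "simulate",
                             list(scenario = scenario),
                             list(pi = pi, delta1 = delta1, gamma1 = gamma1,
                                  delta2 = delta2, gamma2 = gamma2, n = n),
                             seed, list(table = tab_path))
  invisible(list(table = tab_path, manifest = manifest))
}
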