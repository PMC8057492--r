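#' Construct a 2x2 cross-classification of two binary diagnostic measures
#'
#' Container for the four cell counts obtained by cross-classifying two
#' binary diagnostic measures on one sample. The convention throughout the
#' package is measure 1 = the administrative measure, measure 2 = the survey
#' measure.
#'
#' @param a Count positive on both measures.
#' @param b Count positive on measure 2 (survey) only.
#' @param c Count positive on measure 1 (administrative) only.
#' @param d Count negative on both measures.
#' @param label_m1,label_m2 Free-text labels for the two measures.
#'
#' @return An object of class `two_by_two`: a list with integer elements
#'   `a`, `b`, `c`, `d`, the labels, and derived `n`.
#' @examples
#' t <- two_by_two(a = 164, b = 413, c = 268, d = 3312)
#' t$n
#' @export
two_by_two <- function(a, b, c, d,
                       label_m1 = "administrative", label_m2 = "survey") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (length(cells) != 4L || anyNA(cells) || !is_whole(cells))
    stop_validation("cell counts must be four non-missing integers")
  if (any(cells < 0))
    stop_validation("cell counts must be non-negative")
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  if (sum(cells) == 0L)
    stop_validation("total sample size must be positive")
  structure(
    list(a = cells[["a"]], b = cells[["b"]], c = cells[["c"]], d = cells[["d"]],
         n = sum(cells), label_m1 = label_m1, label_m2 = label_m2),
    class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 cross-classification (n = %d)\n", x$n))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(paste(x$label_m1, c("+", "-")),
                              paste(x$label_m2, c("+", "-"))))
  print(m)
  invisible(x)
}

cells_vector <- function(t) c(a = t$a, b = t$b, c = t$c, d = t$d)

#' Read a 2x2 cross-classification from a file
#'
#' Accepts a CSV with header `a,b,c,d`, or JSON/YAML with either the four
#' cell keys `{a,b,c,d}` or printed margins
#' `{n, p_admin, p_survey, concordance, definition}` (the latter solved by
#' [crosstab_from_margins()]).
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (by extension), `"csv"`, `"json"`, `"yaml"`.
#' @return A [two_by_two()] table.
#' @export
read_crosstab <- function(path, format = c("auto", "csv", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_io("file not found: %s", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     yaml = , yml = "yaml",
                     stop_io("cannot infer format from extension of '%s'", path))
  }
  x <- switch(format,
    csv = {
      df <- tryCatch(read.csv(path), error = function(e)
        stop_io("failed to parse CSV '%s': %s", path, conditionMessage(e)))
      if (nrow(df) < 1L) stop_io("CSV '%s' has no rows", path)
      as.list(df[1L, , drop = FALSE])
    },
    json = tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop_io("failed to parse JSON '%s': %s", path, conditionMessage(e))),
    yaml = tryCatch(fix_yaml_n(yaml::read_yaml(path)), error = function(e)
      stop_io("failed to parse YAML '%s': %s", path, conditionMessage(e))))
  if (all(c("a", "b", "c", "d") %in% names(x))) {
    two_by_two(a = x$a, b = x$b, c = x$c, d = x$d,
               label_m1 = x$label_m1 %||% "administrative",
               label_m2 = x$label_m2 %||% "survey")
  } else if (all(c("n", "p_admin", "p_survey", "concordance") %in% names(x))) {
    crosstab_from_margins(n = x$n, p_m1 = x$p_admin, p_m2 = x$p_survey,
                          concordance = x$concordance,
                          definition = x$definition %||% "positive_agreement")
  } else {
    stop_validation("file must declare cells {a,b,c,d} or margins {n,p_admin,p_survey,concordance}")
  }
}

#' Solve the 2x2 cell counts from printed margins
#'
#' Published analyses often report only the two apparent prevalences and a
#' concordance statistic. Given those margins this solves the unique integer
#' table consistent with them. Under positive agreement
#' (`a / (a + b + c)`), the both-positive count solves
#' `a = conc * (m1_pos + m2_pos - a)`; under Cohen's kappa the observed
#' agreement is recovered from kappa and the margin-expected agreement.
#' The remaining cells follow by subtraction, and the reconstructed margins
#' are checked against the inputs (tolerance 0.001 on each proportion).
#'
#' @param n Total sample size.
#' @param p_m1 Apparent prevalence on measure 1 (administrative), either a
#'   proportion or (when greater than 1) the exact count of positives.
#'   A printed proportion identifies the count only up to its rounding
#'   precision, so pass counts when you have them.
#' @param p_m2 Apparent prevalence on measure 2 (survey); proportion or
#'   count, as for `p_m1`.
#' @param concordance The printed concordance statistic.
#' @param definition `"positive_agreement"` (default) or `"cohen_kappa"`.
#' @param tol Tolerance on reconstructed margins/concordance.
#' @return A [two_by_two()] table.
#' @examples
#' crosstab_from_margins(4157, p_m1 = 432, p_m2 = 577, concordance = 0.194)
#' @export
crosstab_from_margins <- function(n, p_m1, p_m2, concordance,
                                  definition = c("positive_agreement", "cohen_kappa"),
                                  tol = 1e-3) {
  definition <- match.arg(definition)
  if (!is_whole(n) || n <= 0) stop_validation("n must be a positive integer")
  as_count <- function(p, what) {
    if (p < 0) stop_validation("%s must be non-negative", what)
    if (p <= 1) return(round(p * n))
    if (!is_whole(p) || p > n)
      stop_validation("%s given as a count must be an integer <= n", what)
    round(p)
  }
  if (definition == "positive_agreement" && (concordance < 0 || concordance > 1))
    stop_validation("positive agreement must lie in [0, 1]")
  m1_pos <- as_count(p_m1, "p_m1")
  m2_pos <- as_count(p_m2, "p_m2")
  p_m1 <- m1_pos / n
  p_m2 <- m2_pos / n
  if (definition == "positive_agreement") {
    # a = conc * (m1_pos + m2_pos - a)  =>  a = conc (m1+m2) / (1 + conc)
    a <- round(concordance * (m1_pos + m2_pos) / (1 + concordance))
  } else {
    # kappa = (p_o - p_e) / (1 - p_e) with p_e fixed by the margins;
    # a + d = n p_o and d = n - m1_pos - m2_pos + a give a.
    p_e <- (m1_pos * m2_pos + (n - m1_pos) * (n - m2_pos)) / n^2
    p_o <- concordance * (1 - p_e) + p_e
    a <- round((n * p_o - n + m1_pos + m2_pos) / 2)
  }
  lo <- max(0, m1_pos + m2_pos - n)
  hi <- min(m1_pos, m2_pos)
  if (a < lo || a > hi)
    stop_validation("margins are inconsistent: solved both-positive count %d outside [%d, %d]",
                    a, lo, hi)
  t <- two_by_two(a = a, b = m2_pos - a, c = m1_pos - a,
                  d = n - m1_pos - m2_pos + a)
  # round-trip check against the printed inputs
  ok <- abs((t$a + t$c) / n - p_m1) <= tol + 0.5 / n &&
    abs((t$a + t$b) / n - p_m2) <= tol + 0.5 / n &&
    abs(concordance(t, definition) - concordance) <= tol + 1 / (t$a + t$b + t$c)
  if (!ok)
    stop_validation("no integer table reproduces the stated margins within tolerance")
  t
}

#' Apparent prevalence of one measure with a Wald interval
#'
#' The raw proportion testing positive on one measure, with the unweighted
#' Wald normal-approximation interval `p +/- 1.96 sqrt(p(1-p)/n)` truncated
#' to `[0, 1]`. This is the frequentist "apparent" prevalence; under
#' misclassification it is a biased estimate of the true prevalence (see
#' [rogan_gladen()]).
#'
#' @param t A [two_by_two()] table.
#' @param which `"m1"` (administrative) or `"m2"` (survey).
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with `statistic`, `estimate`, `lower`, `upper`.
#' @examples
#' t <- two_by_two(164, 413, 268, 3312)
#' prevalence(t, "m2")  # survey-derived
#' @export
prevalence <- function(t, which = c("m1", "m2"), conf_level = 0.95) {
  which <- match.arg(which)
  stopifnot(inherits(t, "two_by_two"))
  k <- if (which == "m1") t$a + t$c else t$a + t$b
  p <- k / t$n
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / t$n)
  data.frame(statistic = paste0("prevalence_", which),
             estimate = p,
             lower = max(0, p - half),
             upper = min(1, p + half))
}

#' Agreement between the two measures
#'
#' `positive_agreement` is the Jaccard-type concordance
#' `a / (a + b + c)`: among people positive on at least one measure, the
#' proportion positive on both. `cohen_kappa` is chance-corrected overall
#' agreement `(p_o - p_e) / (1 - p_e)`.
#'
#' @param t A [two_by_two()] table.
#' @param definition `"positive_agreement"` (default) or `"cohen_kappa"`.
#' @return The agreement statistic (scalar).
#' @examples
#' t <- two_by_two(164, 413, 268, 3312)
#' concordance(t)                  # 0.194
#' concordance(t, "cohen_kappa")   # about 0.23
#' @export
concordance <- function(t, definition = c("positive_agreement", "cohen_kappa")) {
  definition <- match.arg(definition)
  stopifnot(inherits(t, "two_by_two"))
  if (definition == "positive_agreement") {
    denom <- t$a + t$b + t$c
    if (denom == 0)
      stop_validation("positive agreement undefined: no one positive on either measure")
    t$a / denom
  } else {
    n <- t$n
    p_o <- (t$a + t$d) / n
    m1_pos <- t$a + t$c
    m2_pos <- t$a + t$b
    p_e <- (m1_pos * m2_pos + (n - m1_pos) * (n - m2_pos)) / n^2
    if (p_e == 1) stop_validation("kappa undefined: degenerate margins")
    (p_o - p_e) / (1 - p_e)
  }
}

#' Tidy frequentist descriptives for a 2x2 cross-classification
#'
#' Both apparent prevalences with Wald intervals plus the concordance, in a
#' tidy one-row-per-statistic data frame ready for `write.csv()`.
#'
#' @inheritParams prevalence
#' @param definition Concordance definition, as in [concordance()].
#' @return Data frame with columns `statistic`, `estimate`, `lower`, `upper`.
#' @export
descriptive_stats <- function(t, conf_level = 0.95,
                              definition = "positive_agreement") {
  conc <- data.frame(statistic = paste0("concordance_", definition),
                     estimate = concordance(t, definition),
                     lower = NA_real_, upper = NA_real_)
  rbind(prevalence(t, "m1", conf_level), prevalence(t, "m2", conf_level), conc)
}
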