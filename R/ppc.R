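#' Posterior predictive draws of the 2x2 cell counts
#'
#' For each retained posterior draw (all chains pooled, no thinning) one
#' replicate table is simulated as a multinomial of size `n` with the cell
#' probabilities implied by that draw. Rows are predictive tables, columns
#' the cells `a`, `b`, `c`, `d`.
#'
#' @param fit A two-measure [fit_prevalence()] result.
#' @param n Table total; defaults to the fitted table's `n`.
#' @param seed Seed for the predictive simulation (defaults to the
#'   sampler's master seed plus one).
#' @return Integer matrix `n_total_draws x 4` with columns `a,b,c,d`; each
#'   row sums to `n`.
#' @export
posterior_predictive <- function(fit, n = NULL, seed = NULL) {
  stopifnot(inherits(fit, "prevalence_fit"))
  if (fit$model != "two_measure")
    stop_validation("posterior predictive checks apply to the two-measure model")
  n <- n %||% fit$table$n
  if (n <= 0) stop_validation("n must be positive")
  seed <- seed %||% (fit$config$seed + 1L)
  theta <- full_param_draws(fit)
  set.seed(seed)
  out <- matrix(0L, nrow(theta), 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (i in seq_len(nrow(theta))) {
    p <- cell_probs(theta[i, ])
    # cell order a,b,c,d corresponds to patterns p11, p01, p10, p00
    out[i, ] <- rmultinom(1, n, p[c("p11", "p01", "p10", "p00")])[, 1]
  }
  out
}

#' Summarise a posterior predictive check
#'
#' Per-cell predictive mean and 95% equally tailed interval (same quantile
#' rule as [posterior_summary()]), with a flag for whether the observed
#' count falls inside its interval. The check statistic is the raw cell
#' count. Also reports the predictive mean of the total-positives statistic
#' `a + b + c`.
#'
#' @param pred Predictive draws from [posterior_predictive()].
#' @param observed The observed [two_by_two()] table.
#' @param prob Interval probability (default 0.95).
#' @return Object of class `ppc_result`: a data frame with columns `cell`,
#'   `observed`, `mean`, `lower`, `upper`, `within_interval`, and attribute
#'   `total_positives_mean`.
#' @examples
#' t <- two_by_two(164, 413, 268, 3312)
#' fit <- fit_prevalence(t, config = sampler_config(2, 200, 200, seed = 1))
#' ppc_summary(posterior_predictive(fit), t)
#' @export
ppc_summary <- function(pred, observed, prob = 0.95) {
  stopifnot(is.matrix(pred), ncol(pred) == 4,
            inherits(observed, "two_by_two"))
  if (nrow(pred) < 1000)
    warning("fewer than 1000 predictive draws; intervals may be unstable")
  alpha <- (1 - prob) / 2
  obs <- cells_vector(observed)
  rows <- lapply(c("a", "b", "c", "d"), function(cell) {
    x <- pred[, cell]
    q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(cell = cell, observed = obs[[cell]], mean = mean(x),
               lower = q[1], upper = q[2],
               within_interval = obs[[cell]] >= q[1] && obs[[cell]] <= q[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "total_positives_mean") <- mean(rowSums(pred[, c("a", "b", "c")]))
  class(out) <- c("ppc_result", class(out))
  out
}

#' Plot a posterior predictive check
#'
#' Dot = predictive mean, whiskers = 95% predictive interval, vertical
#' line = observed count, one panel per cell.
#'
#' @param ppc A [ppc_summary()] result.
#' @return A ggplot object.
#' @export
plot_ppc <- function(ppc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_validation("plotting requires the ggplot2 package")
  df <- as.data.frame(ppc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$cell)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$observed), shape = 124, size = 5) +
    ggplot2::labs(x = "cell count", y = NULL,
                  title = "Posterior predictive check",
                  subtitle = "dot/whiskers = predictive mean and 95% interval; bar = observed")
}
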