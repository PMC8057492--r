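#' Sampler configuration
#'
#' Settings for the multi-chain MCMC run. Defaults mirror a 12-chain run
#' with 1000 warmup and 1000 retained draws per chain.
#'
#' @param n_chains Number of chains (at least 2).
#' @param n_warmup Warmup (adaptation) iterations per chain, discarded.
#' @param n_draws Retained post-warmup draws per chain.
#' @param seed Master seed; per-chain seeds are derived from it
#'   deterministically (see Details).
#' @param algorithm Currently `"adaptive_rw_metropolis"`: random-walk
#'   Metropolis on the logit scale whose proposal covariance is adapted
#'   during warmup only. The argument exists so an external gradient-based
#'   backend can be slotted in without changing call sites.
#' @param target_accept Target acceptance rate for the warmup step-size
#'   adaptation.
#' @param thin Internal thinning of the post-warmup phase: each retained
#'   draw is preceded by `thin` Metropolis steps, so `n_draws` stays the
#'   number of stored draws while their autocorrelation drops. The model is
#'   five-dimensional and each density evaluation is a handful of
#'   arithmetic operations, so the default costs milliseconds.
#'
#' @details Chain `c` uses the `c`-th value of a seed stream generated from
#' the master seed, so increasing `n_chains` leaves the seeds of existing
#' chains unchanged.
#'
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 12, n_warmup = 1000, n_draws = 1000,
                           seed = 1, algorithm = "adaptive_rw_metropolis",
                           target_accept = 0.3, thin = 10) {
  if (!is_whole(n_chains) || n_chains < 2)
    stop_validation("n_chains must be an integer >= 2")
  if (!is_whole(n_warmup) || n_warmup < 1 || !is_whole(n_draws) || n_draws < 1)
    stop_validation("n_warmup and n_draws must be integers >= 1")
  if (!is_whole(seed)) stop_validation("seed must be an integer")
  algorithm <- match.arg(algorithm, "adaptive_rw_metropolis")
  if (target_accept <= 0 || target_accept >= 1)
    stop_validation("target_accept must lie in (0, 1)")
  if (!is_whole(thin) || thin < 1)
    stop_validation("thin must be an integer >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed),
                 algorithm = algorithm,
                 target_accept = target_accept,
                 thin = as.integer(thin)),
            class = "sampler_config")
}

# Deterministic seed stream: element c is chain c's seed and is stable in
# n_chains (the stream is consumed left to right).
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sample a posterior by adaptive random-walk Metropolis
#'
#' Runs `config$n_chains` Metropolis chains on the logit-transformed
#' parameter space (with the log-Jacobian `sum(log theta + log(1 - theta))`
#' added so the draws target the stated density on the constrained scale).
#' During warmup a global step size is tuned by Robbins-Monro towards
#' `target_accept`, and halfway through warmup the proposal's diagonal
#' scales are set from the empirical spread of the warmup draws. Adaptation
#' stops at the end of warmup; only post-warmup draws are stored.
#'
#' @param log_post Function mapping a named parameter vector (constrained
#'   scale, each component in (0, 1)) to a log posterior kernel; `-Inf` is a
#'   legal return and is treated as rejection.
#' @param config A [sampler_config()].
#' @param init Named numeric vector of initial values in (0, 1); each chain
#'   jitters it uniformly by up to 0.05 (clamped to (0.01, 0.99)) and
#'   re-jitters up to 100 times if the log posterior is not finite there.
#' @return Object of class `posterior_draws`: list with `draws` (array
#'   `n_draws x n_chains x n_params` on the constrained scale), `config`,
#'   `accept_rate` (per chain), `seeds`, and `param_names`.
#' @examples
#' lp <- function(th) dbeta(th[["p"]], 3, 5, log = TRUE)
#' d <- sample_posterior(lp, sampler_config(2, 200, 200, seed = 1),
#'                       init = c(p = 0.4))
#' posterior_summary(d)
#' @export
sample_posterior <- function(log_post, config = sampler_config(), init) {
  stopifnot(inherits(config, "sampler_config"))
  if (is.null(names(init)) || anyNA(init) || any(init <= 0) || any(init >= 1))
    stop_validation("init must be a named vector with components in (0, 1)")
  p <- length(init)
  seeds <- derive_seeds(config$seed, config$n_chains)
  draws <- array(NA_real_,
                 dim = c(config$n_draws, config$n_chains, p),
                 dimnames = list(NULL, NULL, names(init)))
  accept <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    res <- run_rw_chain(log_post, init, config, seeds[ch])
    draws[, ch, ] <- res$draws
    accept[ch] <- res$accept
  }
  structure(list(draws = draws, config = config, accept_rate = accept,
                 seeds = seeds, param_names = names(init)),
            class = "posterior_draws")
}

# One adaptive RW Metropolis chain on the logit scale. Warmup runs in two
# phases: a scalar step size tuned by Robbins-Monro throughout, and -- from
# halfway -- a proposal shaped by the Cholesky factor of the empirical
# covariance of the first-phase warmup draws (plus a small ridge), which
# handles the strong posterior correlations between prevalence and the
# specificity parameters. Adaptation freezes at the end of warmup. The
# post-warmup phase takes `thin` Metropolis steps per stored draw.
run_rw_chain <- function(log_post, init, config, chain_seed) {
  set.seed(chain_seed)
  p <- length(init)
  nm <- names(init)
  lp_z <- function(z) {
    th <- plogis(z)
    if (any(th <= 0) || any(th >= 1)) return(-Inf)  # numeric underflow guard
    names(th) <- nm
    log_post(th) + sum(log(th) + log1p(-th))
  }
  # jittered initialisation; retry while the density is degenerate there
  z <- NULL
  for (try in seq_len(100)) {
    th0 <- pmin(0.99, pmax(0.01, init + runif(p, -0.05, 0.05)))
    cand <- qlogis(th0)
    if (is.finite(lp_z(cand))) { z <- cand; break }
  }
  if (is.null(z))
    stop_sampling("initialization failed: log posterior not finite near init after 100 jitters")
  cur <- lp_z(z)
  n_warm <- config$n_warmup
  n_draw <- config$n_draws
  thin <- config$thin
  ls <- log(2.38 / sqrt(p))          # classic RW scaling as a starting point
  chol_L <- diag(p)
  warm_hist <- matrix(NA_real_, n_warm, p)
  out <- matrix(NA_real_, n_draw, p)
  n_acc <- 0L
  n_post <- 0L
  step <- function() {
    zp <- z + exp(ls) * as.vector(chol_L %*% rnorm(p))
    lpp <- lp_z(zp)
    acc <- is.finite(lpp) && log(runif(1)) < lpp - cur
    if (acc) { z <<- zp; cur <<- lpp }
    acc
  }
  for (i in seq_len(n_warm)) {
    acc <- step()
    warm_hist[i, ] <- z
    ls <- ls + (as.numeric(acc) - config$target_accept) / sqrt(i)
    if (i == max(4L, n_warm %/% 2L) && p > 1) {
      S <- var(warm_hist[seq_len(i), , drop = FALSE])
      S <- S + diag(1e-6 + 1e-3 * mean(diag(S)), p)
      L <- chol(S)
      # normalise so ls keeps carrying the overall magnitude
      scale0 <- exp(mean(log(diag(L))))
      chol_L <- t(L) / scale0
    }
  }
  for (j in seq_len(n_draw)) {
    for (k in seq_len(thin)) {
      n_acc <- n_acc + as.integer(step())
      n_post <- n_post + 1L
    }
    out[j, ] <- plogis(z)
  }
  list(draws = out, accept = n_acc / n_post)
}

as_chain_matrix <- function(draws, parameter) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% draws$param_names)
    stop_validation("unknown parameter '%s'", parameter)
  draws$draws[, , parameter, drop = TRUE]
}

# Split each chain in half (dropping one draw from odd-length chains) so
# within-chain trends register as between-chain disagreement.
split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  if (half < 2L) stop_validation("need at least 4 draws per chain")
  cbind(m[seq_len(half), , drop = FALSE],
        m[(n - half + 1L):n, , drop = FALSE])
}

#' Split-chain Gelman-Rubin diagnostic (R-hat)
#'
#' The classic potential scale reduction factor computed on split chains
#' (each chain halved, so slow trends within a chain inflate the
#' statistic). Not the rank-normalised variant: R-hat here is
#' `sqrt(((n-1)/n W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of the split-chain means. Values
#' below 1.01 are conventionally taken as evidence of convergence.
#'
#' @param draws A [sample_posterior()] result.
#' @param parameter Parameter name.
#' @return R-hat (scalar); `NaN` with a warning if all chains are constant.
#' @export
gelman_rubin <- function(draws, parameter) {
  m <- split_chains(as_chain_matrix(draws, parameter))
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (W == 0) {
    warning("constant chains: R-hat undefined")
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of an MCMC parameter
#'
#' Autocorrelation-based ESS across split chains, following the combined
#' multi-chain estimator: lag-`t` correlations are estimated from the mean
#' within-chain autocovariance relative to the pooled variance, summed with
#' Geyer's initial monotone positive-pair truncation, and
#' `ESS = M n / (1 + 2 sum rho)`. Capped at the total number of draws.
#'
#' @inheritParams gelman_rubin
#' @return List with `ess` and `ratio` (ESS / total post-warmup draws).
#' @export
effective_sample_size <- function(draws, parameter) {
  m <- split_chains(as_chain_matrix(draws, parameter))
  n <- nrow(m)
  M <- ncol(m)
  total <- length(as_chain_matrix(draws, parameter))
  W <- mean(apply(m, 2, var))
  if (W == 0) {
    warning("constant chains: ESS undefined")
    return(list(ess = NaN, ratio = NaN))
  }
  B <- n * var(colMeans(m))
  var_hat <- (n - 1) / n * W + B / n
  # mean within-chain autocovariance at each lag
  acov <- sapply(seq_len(M), function(ch)
    acf(m[, ch], lag.max = n - 1, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1])
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_hat     # rho[1] is lag 0 (== not 1 exactly)
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- min(total, M * n / (1 + 2 * tau))
  list(ess = ess, ratio = ess / total)
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, median, 95% equally tailed credible
#' interval (2.5% and 97.5% empirical quantiles, linear interpolation of
#' order statistics -- R quantile type 7), split-chain R-hat and effective
#' sample size.
#'
#' @param draws A [sample_posterior()] result.
#' @param prob Central interval probability (default 0.95).
#' @return Data frame with one row per parameter: `parameter`, `mean`,
#'   `median`, `ci_low`, `ci_high`, `rhat`, `ess`, `ess_ratio`.
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  alpha <- (1 - prob) / 2
  rows <- lapply(draws$param_names, function(nm) {
    x <- as.vector(as_chain_matrix(draws, nm))
    q <- quantile(x, c(alpha, 0.5, 1 - alpha), names = FALSE, type = 7)
    es <- effective_sample_size(draws, nm)
    data.frame(parameter = nm, mean = mean(x), median = q[2],
               ci_low = q[1], ci_high = q[3],
               rhat = gelman_rubin(draws, nm),
               ess = es$ess, ess_ratio = es$ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d chains x %d draws, parameters: %s\n",
              x$config$n_chains, x$config$n_draws,
              paste(x$param_names, collapse = ", ")))
  cat(sprintf("mean acceptance rate %.2f\n", mean(x$accept_rate)))
  invisible(x)
}

#' Flatten posterior draws to a data frame
#'
#' One row per (chain, draw) with a column per parameter -- the on-disk
#' draws format used by [run_fit()].
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return Data frame with columns `chain`, `draw`, then parameters.
#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  cfg <- x$config
  base <- data.frame(chain = rep(seq_len(cfg$n_chains), each = cfg$n_draws),
                     draw = rep(seq_len(cfg$n_draws), cfg$n_chains))
  for (nm in x$param_names)
    base[[nm]] <- as.vector(x$draws[, , nm])
  base
}

# Pool all chains into a draws-by-parameter matrix (post-warmup only).
pooled_draws <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  out <- sapply(x$param_names, function(nm) as.vector(x$draws[, , nm]))
  colnames(out) <- x$param_names
  out
}
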