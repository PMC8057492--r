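# Shared fixtures: the study cross-classification, its parameter regime,
# and compact sampler configurations for tests that only need a correct
# posterior, not a publication-grade one.

`%||%` <- function(a, b) if (is.null(a)) b else a

study_table <- function() two_by_two(a = 164, b = 413, c = 268, d = 3312)

study_params <- function() model_params(0.086, 0.629, 0.938, 0.553, 0.937)

# Small-but-mixing config for unit tests.
quick_config <- function(seed = 1, chains = 4, warmup = 400, draws = 400,
                         thin = 3) {
  sampler_config(chains, warmup, draws, seed = seed, thin = thin)
}

# Build a posterior_draws object directly from a draws x chains matrix
# (single parameter) so diagnostics can be tested on hand-made arrays.
fake_draws <- function(m, parameter = "x") {
  arr <- array(m, dim = c(nrow(m), ncol(m), 1),
               dimnames = list(NULL, NULL, parameter))
  structure(list(draws = arr,
                 config = sampler_config(max(2, ncol(m)), 1, nrow(m)),
                 accept_rate = rep(NA_real_, ncol(m)),
                 seeds = seq_len(ncol(m)),
                 param_names = parameter),
            class = "posterior_draws")
}

mcse <- function(draws, parameter) {
  x <- as.vector(draws$draws[, , parameter])
  sd(x) / sqrt(effective_sample_size(draws, parameter)$ess)
}
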