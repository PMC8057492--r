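# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to distinct exit codes.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("latentprev_validation_error", "latentprev_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("latentprev_io_error", "latentprev_error")))
}

stop_sampling <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("latentprev_sampling_error", "latentprev_error")))
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 treats a bare `n` key as boolean FALSE; restore the intended name.
fix_yaml_n <- function(x) {
  names(x)[names(x) %in% c("FALSE", "no")] <- "n"
  x
}
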