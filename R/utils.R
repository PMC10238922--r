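# internal helpers

# Evaluate `code` under a temporary RNG seed when one is given, leaving the
# global RNG state untouched; with seed = NULL the ambient RNG stream is used.
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic child seeds for independent sub-simulations, drawn from the
# current RNG stream (which the caller has already seeded when reproducibility
# is requested). Kept strictly below 2^31 so they are valid R integer seeds.
child_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(TRUE)
}
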