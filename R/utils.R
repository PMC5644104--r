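# Internal helpers: classed error conditions and scoped RNG.

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = "mda_data_error"))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = "mda_usage_error"))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
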