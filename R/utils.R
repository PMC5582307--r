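# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_finite <- function(x, what = "signal") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    rlang::abort(
      sprintf("%s must be numeric and finite throughout", what),
      class = "dusbeats_nonfinite"
    )
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))
samples_to_ms <- function(k, fs) k / fs * 1000
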