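#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so generators are pure functions of (parameters, seed)
#' without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a component sub-seed from a master seed
#'
#' Deterministic splitting of one master seed into independent per-component
#' streams (background noise, event times, phase lags, controller draws), so a
#' single integer reproduces a whole session. Uses a Lehmer-style step modulo
#' the Mersenne prime 2^31 - 1; results always fit in a 32-bit integer.
#'
#' @param seed integer master seed.
#' @param stream integer component index (>= 1).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(stream)) {
    x <- (x * 48271 + 11) %% m
  }
  as.integer(if (x == 0) 1 else x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive number", name), call. = FALSE)
  }
  invisible(x)
}
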