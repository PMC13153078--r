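# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, restoring the caller's state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a given seed always produces bit-identical output and
#' never disturbs the caller's random-number stream.
#'
#' @param seed integer seed; `NULL` leaves the current RNG state untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers/tests can match on error class.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "lpnspec_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
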