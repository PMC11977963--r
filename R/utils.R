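#' Evaluate code with a transient RNG seed
#'
#' All generators in the package are pure functions of their parameters and a
#' seed: the ambient RNG state is saved, the seed applied, and the state
#' restored afterwards. `seed = NULL` uses the ambient RNG unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# stop() with a consistent error class so callers can condition on failures
abort_ss <- function(msg, class) {
  stop(structure(
    class = c(class, "splicescreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Standard error of the mean
#' @param x numeric vector.
#' @return `sd(x)/sqrt(length(x))`; 0 for a single observation.
#' @keywords internal
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}
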