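#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so seeded helpers never perturb the
#' session's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed and a stream label.
# Kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

stop_bpr <- function(fmt, ..., class = "bpr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_that <- function(ok, fmt, ..., class = "bpr_validation_error") {
  if (!isTRUE(ok)) stop_bpr(fmt, ..., class = class)
  invisible(TRUE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Min-max normalize an array to the unit interval
#'
#' A constant-valued input (zero range) is mapped to all zeros rather than
#' dividing by zero.
#'
#' @param x numeric array.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) return(array(0, dim = if (is.null(dim(x))) length(x) else dim(x)))
  (x - lo) / (hi - lo)
}
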