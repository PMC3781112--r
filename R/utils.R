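#' @keywords internal
#' @useDynLib flockpopgen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in this package take an explicit seed and leave
#' the caller's global RNG state untouched. This helper saves `.Random.seed`,
#' seeds the Mersenne-Twister generator, evaluates `expr`, and restores the
#' previous state on exit.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps values in 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Parse numbers that may use comma decimal separators (as printed in some
# published tables). Output formats of this package always use dot decimals.
parse_decimal <- function(x) {
  as.numeric(gsub(",", ".", trimws(as.character(x)), fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
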