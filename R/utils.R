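#' @importFrom rlang .data
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so seeded package functions never perturb the
#' caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG state untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Validate a probability mass function vector; `field` names the offending
# config entry in the error message.
check_pmf <- function(p, field) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop(sprintf("configuration error: '%s' must be a numeric probability vector", field))
  }
  if (any(p < 0)) {
    stop(sprintf("configuration error: '%s' has negative entries", field))
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop(sprintf(
      "configuration error: '%s' must sum to 1 (got %.15g)", field, sum(p)
    ))
  }
  invisible(p)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name))
  }
  invisible(x)
}

#' Round to significant figures for report tables
#'
#' Display rounding used in the human-readable hazard-quotient and cancer-risk
#' tables; machine-readable outputs keep full precision.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (default 2).
#' @return Rounded numeric vector.
#' @export
report_signif <- function(x, digits = 2) signif(x, digits)
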