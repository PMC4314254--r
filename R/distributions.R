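#' Pearson type V (inverse-gamma) distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the Pearson type V distribution, implemented as the inverse-gamma family:
#' if \eqn{Y \sim \mathrm{Gamma}(shape, rate = scale)} then \eqn{X = 1/Y} is
#' Pearson V with the same `shape` and `scale`. The mean is
#' `scale / (shape - 1)` for `shape > 1`.
#'
#' @param x,q Vector of quantiles (positive).
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param shape Shape parameter (> 0).
#' @param scale Scale parameter (> 0).
#' @param log,log.p Logical; return log density / take log probabilities.
#' @return `dpearson5` a density vector, `ppearson5` probabilities,
#'   `qpearson5` quantiles, `rpearson5` random draws.
#' @export
dpearson5 <- function(x, shape, scale, log = FALSE) {
  stopifnot(shape > 0, scale > 0)
  ld <- ifelse(
    x > 0,
    shape * base::log(scale) - lgamma(shape) - (shape + 1) * base::log(x) - scale / x,
    -Inf
  )
  if (log) ld else exp(ld)
}

#' @rdname dpearson5
#' @export
ppearson5 <- function(q, shape, scale, log.p = FALSE) {
  stopifnot(shape > 0, scale > 0)
  p <- ifelse(q > 0, stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE), 0)
  if (log.p) base::log(p) else p
}

#' @rdname dpearson5
#' @export
qpearson5 <- function(p, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  out <- 1 / stats::qgamma(1 - p, shape = shape, rate = scale)
  out[p <= 0] <- 0
  out[p >= 1] <- Inf
  out
}

#' @rdname dpearson5
#' @export
rpearson5 <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' Pearson type VI (scaled beta-prime) distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the Pearson type VI distribution, implemented as the beta-prime family with
#' a scale: if \eqn{Z \sim \mathrm{Beta}(shape1, shape2)} then
#' \eqn{X = scale \cdot Z/(1-Z)} is Pearson VI. The mean is
#' `scale * shape1 / (shape2 - 1)` for `shape2 > 1`.
#'
#' @param x,q Vector of quantiles (positive).
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param shape1,shape2 Shape parameters (> 0).
#' @param scale Scale parameter (> 0).
#' @param log,log.p Logical; return log density / take log probabilities.
#' @return `dpearson6` a density vector, `ppearson6` probabilities,
#'   `qpearson6` quantiles, `rpearson6` random draws.
#' @export
dpearson6 <- function(x, shape1, shape2, scale = 1, log = FALSE) {
  stopifnot(shape1 > 0, shape2 > 0, scale > 0)
  ld <- ifelse(
    x > 0,
    (shape1 - 1) * base::log(x / scale) -
      (shape1 + shape2) * log1p(x / scale) -
      base::log(scale) - lbeta(shape1, shape2),
    -Inf
  )
  if (log) ld else exp(ld)
}

#' @rdname dpearson6
#' @export
ppearson6 <- function(q, shape1, shape2, scale = 1, log.p = FALSE) {
  stopifnot(shape1 > 0, shape2 > 0, scale > 0)
  p <- ifelse(q > 0, stats::pbeta(q / (scale + q), shape1, shape2), 0)
  if (log.p) base::log(p) else p
}

#' @rdname dpearson6
#' @export
qpearson6 <- function(p, shape1, shape2, scale = 1) {
  stopifnot(shape1 > 0, shape2 > 0, scale > 0)
  z <- stats::qbeta(p, shape1, shape2)
  scale * z / (1 - z)
}

#' @rdname dpearson6
#' @export
rpearson6 <- function(n, shape1, shape2, scale = 1) {
  z <- stats::rbeta(n, shape1, shape2)
  scale * z / (1 - z)
}
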