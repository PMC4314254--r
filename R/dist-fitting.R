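#' Parametric distribution families available for exposure-factor modelling
#'
#' Candidate families follow common practice in probabilistic exposure
#' assessment: body weight is typically screened against normal, log-normal
#' and Pearson type V; intake rates against Weibull, log-normal and Pearson
#' type VI. A degenerate `point` family is provided so Monte Carlo engines can
#' be driven with fixed inputs.
#'
#' @format Character vector of family names.
#' @export
dist_families <- c("normal", "lognormal", "pearson5", "weibull", "pearson6",
                   "uniform", "point")

# parameter count per family (point carries no estimated parameters)
family_k <- c(normal = 2, lognormal = 2, pearson5 = 2, weibull = 2,
              pearson6 = 3, uniform = 2, point = 0)

#' Construct a fitted-distribution object
#'
#' Container for a parametric family, its estimated parameters, fit statistics
#' and an optional truncation interval. BIC is computed as
#' `k * log(n) - 2 * log_likelihood` with `k` the family's parameter count.
#'
#' @param family One of [dist_families].
#' @param parameters Named numeric vector of family parameters
#'   (`normal`: mean, sd; `lognormal`: meanlog, sdlog; `weibull`: shape,
#'   scale; `pearson5`: shape, scale; `pearson6`: shape1, shape2, scale;
#'   `uniform`: min, max; `point`: value).
#' @param log_likelihood Log-likelihood at the parameters (NA for `point`).
#' @param n Sample size the fit was based on (NA for distributions specified
#'   rather than fitted).
#' @param truncation Optional numeric `c(lower, upper)` bounds.
#' @return An object of class `fitted_dist`.
#' @export
fitted_dist <- function(family, parameters, log_likelihood = NA_real_,
                        n = NA_real_, truncation = NULL) {
  family <- match.arg(family, dist_families)
  parameters <- unlist(parameters)
  expected <- switch(family,
    normal    = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    weibull   = c("shape", "scale"),
    pearson5  = c("shape", "scale"),
    pearson6  = c("shape1", "shape2", "scale"),
    uniform   = c("min", "max"),
    point     = "value"
  )
  if (!setequal(names(parameters), expected)) {
    stop(sprintf("family '%s' expects parameters: %s", family,
                 paste(expected, collapse = ", ")))
  }
  parameters <- parameters[expected]
  scale_pars <- intersect(names(parameters),
                          c("sd", "sdlog", "shape", "scale", "shape1", "shape2"))
  if (any(parameters[scale_pars] <= 0)) {
    stop(sprintf("family '%s': scale/shape parameters must be strictly positive", family))
  }
  if (family == "uniform" && parameters["min"] >= parameters["max"]) {
    stop("uniform family requires min < max")
  }
  if (!is.null(truncation)) {
    truncation <- as.numeric(truncation)
    if (length(truncation) != 2L || !(truncation[1] < truncation[2])) {
      stop("truncation must be c(lower, upper) with lower < upper")
    }
  }
  k <- family_k[[family]]
  bic <- if (is.na(log_likelihood) || is.na(n)) NA_real_ else
    k * log(n) - 2 * log_likelihood
  structure(
    list(family = family, parameters = parameters,
         log_likelihood = log_likelihood, bic = bic, n = n, k = k,
         truncation = truncation),
    class = "fitted_dist"
  )
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("<fitted_dist> %s(%s)\n", x$family,
              paste(sprintf("%s=%.6g", names(x$parameters), x$parameters),
                    collapse = ", ")))
  if (!is.null(x$truncation)) {
    cat(sprintf("  truncated to (%g, %g)\n", x$truncation[1], x$truncation[2]))
  }
  if (!is.na(x$log_likelihood)) {
    cat(sprintf("  logLik %.4f  BIC %.4f  n %d\n", x$log_likelihood, x$bic,
                as.integer(x$n)))
  }
  invisible(x)
}

#' Degenerate (point-mass) distribution
#'
#' @param value The constant every draw returns.
#' @return A `fitted_dist` of family `point`.
#' @export
point_dist <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  fitted_dist("point", c(value = value))
}

# log-density of a family at given parameters (untruncated)
dist_logdens <- function(x, family, par) {
  switch(family,
    normal    = stats::dnorm(x, par["mean"], par["sd"], log = TRUE),
    lognormal = stats::dlnorm(x, par["meanlog"], par["sdlog"], log = TRUE),
    weibull   = stats::dweibull(x, par["shape"], par["scale"], log = TRUE),
    pearson5  = dpearson5(x, par["shape"], par["scale"], log = TRUE),
    pearson6  = dpearson6(x, par["shape1"], par["shape2"], par["scale"], log = TRUE),
    uniform   = stats::dunif(x, par["min"], par["max"], log = TRUE),
    stop(sprintf("no density available for family '%s'", family))
  )
}

dist_cdf <- function(q, family, par) {
  switch(family,
    normal    = stats::pnorm(q, par["mean"], par["sd"]),
    lognormal = stats::plnorm(q, par["meanlog"], par["sdlog"]),
    weibull   = stats::pweibull(q, par["shape"], par["scale"]),
    pearson5  = ppearson5(q, par["shape"], par["scale"]),
    pearson6  = ppearson6(q, par["shape1"], par["shape2"], par["scale"]),
    uniform   = stats::punif(q, par["min"], par["max"]),
    stop(sprintf("no CDF available for family '%s'", family))
  )
}

dist_quantile <- function(p, family, par) {
  switch(family,
    normal    = stats::qnorm(p, par["mean"], par["sd"]),
    lognormal = stats::qlnorm(p, par["meanlog"], par["sdlog"]),
    weibull   = stats::qweibull(p, par["shape"], par["scale"]),
    pearson5  = qpearson5(p, par["shape"], par["scale"]),
    pearson6  = qpearson6(p, par["shape1"], par["shape2"], par["scale"]),
    uniform   = stats::qunif(p, par["min"], par["max"]),
    stop(sprintf("no quantile function available for family '%s'", family))
  )
}

positive_support <- function(family) {
  family %in% c("lognormal", "weibull", "pearson5", "pearson6")
}

#' Maximum-likelihood fit of a parametric family
#'
#' Normal, log-normal and uniform estimates are closed form; the Weibull fit
#' is delegated to [fitdistrplus::fitdist()]; Pearson type V (inverse-gamma)
#' and type VI (scaled beta-prime) are fitted by numerical likelihood
#' maximisation from method-of-moments starting values, so repeated fits of
#' the same sample are identical. The maximised log-likelihood is always
#' recomputed as the sum of log-densities at the returned estimates.
#'
#' @param x Numeric sample (strictly positive for positive-support families).
#' @param family One of `normal`, `lognormal`, `weibull`, `pearson5`,
#'   `pearson6`, `uniform`.
#' @return A [fitted_dist()].
#' @export
#' @examples
#' fit_mle(c(1, 2, 3, 4, 5), "normal")
fit_mle <- function(x, family) {
  family <- match.arg(family, setdiff(dist_families, "point"))
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x) || any(!is.finite(x))) {
    stop("fit_mle requires at least 2 finite, non-missing observations")
  }
  n <- length(x)
  if (positive_support(family) && any(x <= 0)) {
    stop(sprintf("family '%s' has positive support but the sample contains values <= 0", family))
  }
  if (stats::sd(x) < sqrt(.Machine$double.eps) * max(1, abs(mean(x)))) {
    stop("degenerate sample: zero variance, no parametric fit is identifiable")
  }

  par <- switch(family,
    normal = c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2))),
    lognormal = {
      lx <- log(x)
      c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    uniform = c(min = min(x), max = max(x)),
    weibull = {
      fit <- fitdistrplus::fitdist(x, "weibull")
      stats::setNames(fit$estimate[c("shape", "scale")], c("shape", "scale"))
    },
    pearson5 = fit_pearson5(x),
    pearson6 = fit_pearson6(x)
  )
  ll <- sum(dist_logdens(x, family, par))
  if (!is.finite(ll)) {
    stop(sprintf("fit of family '%s' did not converge to a finite likelihood (parameters: %s)",
                 family, paste(sprintf("%.4g", par), collapse = ", ")))
  }
  fitted_dist(family, par, log_likelihood = ll, n = n)
}

# Pearson V MLE: method-of-moments start, Nelder-Mead on log-parameters.
fit_pearson5 <- function(x) {
  m <- mean(x); v <- stats::var(x)
  a0 <- m^2 / v + 2
  b0 <- m * (a0 - 1)
  nll <- function(lp) -sum(dpearson5(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  opt <- stats::optim(c(log(a0), log(b0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop(sprintf("pearson5 fit failed to converge (optim code %d)", opt$convergence))
  }
  c(shape = exp(opt$par[1]), scale = exp(opt$par[2]))
}

# Pearson VI MLE: start from moments with scale pinned at the sample mean
# (shape1 = shape2 - 1 makes the mean equal the scale), then free optimisation.
fit_pearson6 <- function(x) {
  m <- mean(x); v <- stats::var(x)
  b0 <- max(2.5, 2 * m^2 / v + 2)
  a0 <- b0 - 1
  nll <- function(lp) -sum(dpearson6(x, exp(lp[1]), exp(lp[2]), exp(lp[3]), log = TRUE))
  opt <- stats::optim(c(log(a0), log(b0), log(m)), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop(sprintf("pearson6 fit failed to converge (optim code %d)", opt$convergence))
  }
  c(shape1 = exp(opt$par[1]), shape2 = exp(opt$par[2]), scale = exp(opt$par[3]))
}

#' Fit several families and rank them by BIC
#'
#' Fits each candidate family by [fit_mle()] and orders the results by
#' ascending BIC (`k log n - 2 logLik`); ties are broken by higher
#' log-likelihood, then family name. A family whose fit fails is kept at the
#' bottom of the ranking with its error message recorded, so a single
#' ill-conditioned candidate never aborts the screening.
#'
#' @param x Numeric sample.
#' @param families Character vector of at least two candidate families.
#' @return A list of class `fit_ranking`: element `fits` holds the successful
#'   [fitted_dist()] objects in rank order, element `table` a tibble with one
#'   row per candidate (family, log_likelihood, bic, error).
#' @export
rank_fits <- function(x, families) {
  if (length(families) < 2L) stop("rank_fits requires at least two candidate families")
  fits <- lapply(families, function(f) tryCatch(fit_mle(x, f), error = identity))
  ok <- !vapply(fits, inherits, logical(1), "condition")
  tab <- tibble::tibble(
    family = as.character(families),
    log_likelihood = vapply(fits, function(f) if (inherits(f, "fitted_dist")) f$log_likelihood else NA_real_, 0),
    bic = vapply(fits, function(f) if (inherits(f, "fitted_dist")) f$bic else NA_real_, 0),
    error = vapply(fits, function(f) if (inherits(f, "condition")) conditionMessage(f) else NA_character_, "")
  )
  ord <- order(!ok, tab$bic, -tab$log_likelihood, tab$family)
  structure(
    list(fits = fits[ord][ok[ord]], table = tab[ord, ]),
    class = "fit_ranking"
  )
}

#' @export
print.fit_ranking <- function(x, ...) {
  cat("<fit_ranking> families by ascending BIC:\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Best-ranked fit from a ranking
#'
#' @param ranking A `fit_ranking` from [rank_fits()].
#' @return The top-ranked [fitted_dist()].
#' @export
best_fit <- function(ranking) {
  stopifnot(inherits(ranking, "fit_ranking"))
  if (length(ranking$fits) == 0L) stop("no family fitted successfully")
  ranking$fits[[1L]]
}

#' Attach a truncation interval to a fitted distribution
#'
#' Draws from the truncated distribution target the renormalised density on
#' `(lower, upper)`; used for body weight, which is modelled as a normal
#' truncated to physiologically plausible bounds.
#'
#' @param dist A [fitted_dist()].
#' @param lower,upper Truncation bounds, `lower < upper`.
#' @return The distribution with truncation set.
#' @export
truncate_dist <- function(dist, lower, upper) {
  stopifnot(inherits(dist, "fitted_dist"))
  if (dist$family == "point") stop("a point distribution cannot be truncated")
  fitted_dist(dist$family, dist$parameters, dist$log_likelihood, dist$n,
              truncation = c(lower, upper))
}

#' Draw samples from a fitted distribution
#'
#' Sampling is by inversion: uniforms are mapped through the family quantile
#' function, restricted to the truncation interval's quantile range when a
#' truncation is set, so every draw lies strictly inside the bounds and
#' targets the truncated density.
#'
#' @param dist A [fitted_dist()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied, draws are reproducible
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "fitted_dist"), n >= 1)
  if (dist$family == "point") return(rep(dist$parameters[["value"]], n))
  plo <- 0; phi <- 1
  if (!is.null(dist$truncation)) {
    plo <- dist_cdf(dist$truncation[1], dist$family, dist$parameters)
    phi <- dist_cdf(dist$truncation[2], dist$family, dist$parameters)
    if (phi - plo < 1e-12) {
      stop("truncation interval carries (near-)zero probability mass under the fitted family")
    }
  }
  with_seed(seed, {
    u <- stats::runif(n, plo, phi)
    dist_quantile(u, dist$family, dist$parameters)
  })
}

#' Distribution mean implied by a fitted distribution
#'
#' Analytic untruncated mean where it exists; used for deterministic point
#' evaluations alongside Monte Carlo runs.
#'
#' @param dist A [fitted_dist()].
#' @return The mean.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "fitted_dist"))
  p <- dist$parameters
  switch(dist$family,
    point     = p[["value"]],
    normal    = p[["mean"]],
    lognormal = exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2),
    weibull   = p[["scale"]] * gamma(1 + 1 / p[["shape"]]),
    uniform   = (p[["min"]] + p[["max"]]) / 2,
    pearson5  = if (p[["shape"]] > 1) p[["scale"]] / (p[["shape"]] - 1) else
      stop("pearson5 mean undefined for shape <= 1"),
    pearson6  = if (p[["shape2"]] > 1) p[["scale"]] * p[["shape1"]] / (p[["shape2"]] - 1) else
      stop("pearson6 mean undefined for shape2 <= 1")
  )
}

#' Serialise a fitted distribution to JSON
#'
#' @param dist A [fitted_dist()].
#' @return A JSON string (family, parameters, fit statistics, truncation).
#' @export
dist_to_json <- function(dist) {
  stopifnot(inherits(dist, "fitted_dist"))
  jsonlite::toJSON(
    list(family = dist$family, parameters = as.list(dist$parameters),
         log_likelihood = dist$log_likelihood, bic = dist$bic, n = dist$n,
         truncation = dist$truncation),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

#' Deserialise a fitted distribution from JSON
#'
#' @param json A JSON string produced by [dist_to_json()].
#' @return A [fitted_dist()].
#' @export
dist_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  d <- fitted_dist(obj$family, unlist(obj$parameters),
                   log_likelihood = obj$log_likelihood %||% NA_real_,
                   n = obj$n %||% NA_real_,
                   truncation = obj$truncation)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
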