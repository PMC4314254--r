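test_that("closed-form MLEs match hand arithmetic", {
  f <- fit_mle(c(1, 2, 3, 4, 5), "normal")
  expect_equal(unname(f$parameters["mean"]), 3)
  expect_equal(unname(f$parameters["sd"])^2, 2)  # MLE variance, not n-1
  # log-likelihood equals the sum of log-densities at the estimate
  expect_equal(f$log_likelihood,
               sum(stats::dnorm(1:5, 3, sqrt(2), log = TRUE)), tolerance = 1e-10)
  expect_equal(f$bic, 2 * log(5) - 2 * f$log_likelihood)

  x <- exp(c(0.3, 1.1, 2.0, 0.7, 1.5))
  g <- fit_mle(x, "lognormal")
  expect_equal(unname(g$parameters["meanlog"]), mean(log(x)))
  expect_equal(unname(g$parameters["sdlog"]),
               sqrt(mean((log(x) - mean(log(x)))^2)))
})

test_that("degenerate and invalid samples are rejected", {
  expect_error(fit_mle(rep(exp(1), 20), "lognormal"), "degenerate")
  expect_error(fit_mle(c(-1, 2, 3, 4, 5, 6, 7, 8, 9, 10), "weibull"),
               "positive support")
})

test_that("MLE recovers known parameters from large samples", {
  set.seed(101)
  x <- stats::rlnorm(10000, 3.8, 0.3)
  f <- fit_mle(x, "lognormal")
  expect_lt(abs(f$parameters["meanlog"] - 3.8) / 3.8, 0.02)
  expect_lt(abs(f$parameters["sdlog"] - 0.3) / 0.3, 0.02)

  w <- stats::rweibull(10000, shape = 2, scale = 50)
  fw <- fit_mle(w, "weibull")
  expect_lt(abs(fw$parameters["shape"] - 2) / 2, 0.02)
  expect_lt(abs(fw$parameters["scale"] - 50) / 50, 0.02)

  # Pearson V: inverse-gamma draws via reciprocal gamma
  p5 <- 1 / stats::rgamma(10000, shape = 6, rate = 250)
  f5 <- fit_mle(p5, "pearson5")
  expect_lt(abs(f5$parameters["shape"] - 6) / 6, 0.05)
  expect_lt(abs(f5$parameters["scale"] - 250) / 250, 0.05)
})

test_that("weibull and lognormal fits agree with fitdistrplus", {
  set.seed(77)
  x <- stats::rweibull(2000, 1.7, 40)
  f <- fit_mle(x, "weibull")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(f$parameters[c("shape", "scale")]),
               unname(ref$estimate[c("shape", "scale")]), tolerance = 1e-6)
  expect_equal(f$log_likelihood, as.numeric(stats::logLik(ref)), tolerance = 1e-6)

  y <- stats::rlnorm(2000, 1, 0.4)
  g <- fit_mle(y, "lognormal")
  ref2 <- fitdistrplus::fitdist(y, "lnorm")
  expect_equal(unname(g$parameters[c("meanlog", "sdlog")]),
               unname(ref2$estimate[c("meanlog", "sdlog")]), tolerance = 1e-4)
})

test_that("pearson distribution functions are internally consistent", {
  # p is the integral of d (numeric quadrature oracle) and q inverts p
  for (q in c(0.5, 1, 2, 5)) {
    num <- stats::integrate(dpearson5, 0, q, shape = 3, scale = 4,
                            rel.tol = 1e-10)$value
    expect_equal(ppearson5(q, 3, 4), num, tolerance = 1e-7)
    num6 <- stats::integrate(dpearson6, 0, q, shape1 = 2, shape2 = 4,
                             scale = 3, rel.tol = 1e-10)$value
    expect_equal(ppearson6(q, 2, 4, 3), num6, tolerance = 1e-7)
  }
  p <- c(0.05, 0.25, 0.5, 0.9, 0.99)
  expect_equal(ppearson5(qpearson5(p, 3, 4), 3, 4), p, tolerance = 1e-10)
  expect_equal(ppearson6(qpearson6(p, 2, 4, 3), 2, 4, 3), p, tolerance = 1e-10)
})

test_that("BIC ranking prefers the generating family", {
  set.seed(5)
  xn <- stats::rnorm(5000, 63, 11)
  rk <- rank_fits(xn, c("normal", "lognormal", "pearson5"))
  expect_equal(rk$table$family[1], "normal")
  expect_true(all(diff(rk$table$bic) >= 0))

  xw <- stats::rweibull(5000, 2, 50)
  rkw <- rank_fits(xw, c("weibull", "lognormal", "pearson6"))
  expect_equal(rkw$table$family[1], "weibull")
})

test_that("a failing family is ranked last with its error recorded", {
  set.seed(8)
  x <- stats::rnorm(200, 0, 1)  # contains negatives: positive-support fits fail
  rk <- rank_fits(x, c("normal", "lognormal"))
  expect_equal(rk$table$family[1], "normal")
  expect_true(is.na(rk$table$bic[2]))
  expect_match(rk$table$error[2], "positive support")
  expect_equal(best_fit(rk)$family, "normal")
})

test_that("duplicate candidate families keep a stable order", {
  set.seed(9)
  x <- stats::rnorm(500, 10, 2)
  rk <- rank_fits(x, c("normal", "normal"))
  expect_equal(rk$table$family, c("normal", "normal"))
  expect_equal(rk$table$bic[1], rk$table$bic[2])
})

test_that("sampling is deterministic, respects support and truncation", {
  u <- fitted_dist("uniform", c(min = 5, max = 10))
  d4 <- sample_dist(u, 4, seed = 2)
  expect_length(d4, 4)
  expect_true(all(d4 >= 5 & d4 <= 10))
  expect_identical(d4, sample_dist(u, 4, seed = 2))

  tn <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 0, 250)
  x <- sample_dist(tn, 100000, seed = 3)
  expect_true(all(x > 0 & x < 250))
  # truncation at (0, 250) barely shifts a (63, 11) normal's mean
  expect_lt(abs(mean(x) - 63), 0.2)

  expect_error(
    sample_dist(truncate_dist(fitted_dist("normal", c(mean = 0, sd = 1)),
                              500, 600), 10, seed = 1),
    "zero probability")
})

test_that("truncated draws match the analytic truncated CDF", {
  tn <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 40, 90)
  x <- sample_dist(tn, 10000, seed = 12)
  expect_true(all(x > 40 & x < 90))
  plo <- stats::pnorm(40, 63, 11); phi <- stats::pnorm(90, 63, 11)
  tcdf <- function(q) (stats::pnorm(q, 63, 11) - plo) / (phi - plo)
  ks <- max(abs(stats::ecdf(x)(sort(x)) - tcdf(sort(x))))
  expect_lt(ks, 0.02)
})

test_that("fitted distributions round-trip through JSON", {
  d <- truncate_dist(fit_mle(stats::rnorm(100, 63, 11), "normal"), 0, 250)
  d2 <- dist_from_json(dist_to_json(d))
  expect_equal(d2$family, d$family)
  expect_equal(d2$parameters, d$parameters)
  expect_equal(d2$truncation, d$truncation)
  expect_equal(d2$bic, d$bic)
})

test_that("dist_mean matches the analytic means", {
  expect_equal(dist_mean(fitted_dist("uniform", c(min = 5, max = 10))), 7.5)
  expect_equal(dist_mean(fitted_dist("lognormal", c(meanlog = 1, sdlog = 0.5))),
               exp(1 + 0.125))
  expect_equal(dist_mean(fitted_dist("pearson5", c(shape = 3, scale = 4))), 2)
  expect_equal(dist_mean(fitted_dist("pearson6",
                                     c(shape1 = 2, shape2 = 3, scale = 5))), 5)
  expect_equal(dist_mean(point_dist(63)), 63)
})
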