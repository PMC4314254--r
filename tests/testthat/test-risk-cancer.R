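test_that("deterministic risk equation reproduces the published anchor", {
  r <- cancer_risk_point(6.68e-4, 0.0452, 63, 5)
  expect_equal(r, 2.242707e-7, tolerance = 1e-6)
  expect_equal(signif(r, 1), 2e-7)
  expect_equal(cancer_risk_point(0, 0.0452, 63, 5), 0)
  # exposure duration enters linearly
  expect_equal(cancer_risk_point(6.68e-4, 0.0452, 63, 10),
               2 * cancer_risk_point(6.68e-4, 0.0452, 63, 5))
  expect_error(cancer_risk_point(6.68e-4, 0.0452, 63, 100), "lifespan")
})

test_that("risk is proportional to every multiplicative factor", {
  set.seed(21)
  for (i in 1:20) {
    bap <- stats::runif(1, 1e-5, 1e-2); ir <- stats::runif(1, 0.01, 0.2)
    bw <- stats::runif(1, 40, 120); ed <- stats::runif(1, 1, 10)
    osf <- stats::runif(1, 1, 10)
    base <- cancer_risk_point(bap, ir, bw, ed, osf)
    expect_equal(cancer_risk_point(2 * bap, ir, bw, ed, osf), 2 * base)
    expect_equal(cancer_risk_point(bap, 3 * ir, bw, ed, osf), 3 * base)
    expect_equal(cancer_risk_point(bap, ir, 2 * bw, ed, osf), base / 2)
    expect_equal(cancer_risk_point(bap, ir, bw, ed, 2 * osf), 2 * base)
  }
})

test_that("degenerate-input Monte Carlo equals the point computation", {
  cfg <- cancer_model_config(
    bap_eq = 6.68e-4, ir_dist = point_dist(45.2), bw_dist = point_dist(63),
    ed_min = 5, ed_max = 5, n_iter = 200, seed = 1
  )
  s <- cancer_risk_monte_carlo(cfg)
  # the config converts the 45.2 g/day intake to kg/day; the point oracle
  # must see the identically converted value for bitwise agreement
  expect_identical(s$mean, cancer_risk_point(6.68e-4, 45.2 / 1000, 63, 5))
  expect_identical(s$sd, 0)
})

test_that("uniform exposure duration averages to its midpoint risk", {
  cfg <- cancer_model_config(
    bap_eq = 6.68e-4, ir_dist = point_dist(45.2), bw_dist = point_dist(63),
    ed_min = 5, ed_max = 10, n_iter = 10000, seed = 2
  )
  s <- cancer_risk_monte_carlo(cfg)
  mid <- cancer_risk_point(6.68e-4, 0.0452, 63, 7.5)
  expect_lt(abs(s$mean - mid), 3 * s$sd / sqrt(s$n))
})

test_that("MC mean converges to the independence moment product", {
  ir <- fitted_dist("uniform", c(min = 20, max = 70))
  bw <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 0, 250)
  cfg <- cancer_model_config(6.68e-4, ir, bw, n_iter = 10000, seed = 3)
  s <- cancer_risk_monte_carlo(cfg)
  e_inv_bw <- mean(1 / sample_dist(bw, 200000, seed = 99))
  analytic <- 6.68e-4 * (45 / 1000) * 365 * 7.5 / 28470 * e_inv_bw * 7.3
  expect_lt(abs(s$mean - analytic), 3 * s$sd / sqrt(s$n))
})

test_that("histogram frequencies sum to 1 and locate the percentiles", {
  ir <- fitted_dist("uniform", c(min = 20, max = 70))
  bw <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 0, 250)
  cfg <- cancer_model_config(6.68e-4, ir, bw, n_iter = 5000, seed = 7)
  s <- cancer_risk_monte_carlo(cfg)
  h <- s$histogram
  expect_equal(sum(h$rel_freq), 1, tolerance = 1e-9)
  # the p95 falls inside a bin whose cumulative mass brackets 0.95
  cum <- cumsum(h$rel_freq)
  i <- which(h$bin_left <= s$p95 & s$p95 <= h$bin_right)[1]
  expect_gte(cum[i], 0.95 - h$rel_freq[i])
  expect_lte(cum[i] - h$rel_freq[i], 0.95)
})

test_that("common random numbers make tier risks exactly proportional", {
  ir <- fitted_dist("uniform", c(min = 20, max = 70))
  bw <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 0, 250)
  cfg <- cancer_model_config(0, ir, bw, n_iter = 4000, seed = 5)
  bap <- c(a = 1e-3, b = 2.5e-3, c = 5e-3)
  res <- tiered_risk_analysis(config = cfg, tier_bap_eq = bap)
  expect_equal(res$mean[2] / res$mean[1], 2.5, tolerance = 1e-12)
  expect_equal(res$mean[3] / res$mean[1], 5.0, tolerance = 1e-12)
  # ratio preserved in every percentile, not just the mean
  expect_equal(res$p95[2] / res$p95[1], 2.5, tolerance = 1e-12)
  expect_equal(res$p99[3] / res$p99[1], 5.0, tolerance = 1e-12)

  single <- tiered_risk_analysis(config = cfg, tier_bap_eq = bap[1])
  expect_equal(single$mean, res$mean[1])
  expect_error(tiered_risk_analysis(config = cfg, tier_bap_eq = numeric(0)),
               "empty tier")
})

test_that("expanding the analyte tiers raises risk as published", {
  meta <- load_analyte_meta()
  cens <- substitute_nondetects(censored_table(meta, n_samples = 3))
  ir <- fitted_dist("uniform", c(min = 20, max = 70))
  bw <- truncate_dist(fitted_dist("normal", c(mean = 63, sd = 11)), 0, 250)
  cfg <- cancer_model_config(0, ir, bw, n_iter = 4000, seed = 11)
  res <- tiered_risk_analysis(cens, meta, cfg)
  expect_equal(res$tier, c("cpah7", "plus_unsubstituted", "plus_alkylated"))
  expect_equal(res$bap_eq_mg_per_kg[1], 0.668e-3, tolerance = 1e-3)
  # alkylated homologs raise mean and p95 risk by a factor of about 1.5
  expect_equal(res$mean[3] / res$mean[2], 1.5, tolerance = 0.05)
  expect_equal(res$p95[3] / res$p95[2], 1.5, tolerance = 0.05)
  expect_true(all(diff(res$mean) > 0))
})

test_that("synthetic-survey cancer risk lands near the published mean", {
  sv <- generate_survey(survey_gen_config(n_respondents = 2000, seed = 5))
  ir <- fit_mle(intake_table(sv)$rates$intake_g_per_day, "weibull")
  bw <- truncate_dist(fit_mle(sv$body_weight_kg, "normal"), 0, 250)
  cfg <- cancer_model_config(6.68e-4, ir, bw, n_iter = 10000, seed = 8)
  s <- cancer_risk_monte_carlo(cfg)
  expect_lt(s$mean / 2.4e-7, 2)
  expect_gt(s$mean / 2.4e-7, 0.5)
})
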