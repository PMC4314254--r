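#' Deterministic lifetime excess cancer risk
#'
#' Linear slope-factor model: risk = BaPeq (mg/kg shrimp) x intake (kg
#' shrimp/day) x days/year x years exposed / (body weight (kg) x averaging
#' time (days)) x oral slope factor. The default averaging time is a 78-year
#' life span (28,470 days) and exposure is assumed daily (365 days/year).
#'
#' @param bap_eq BaP-equivalent concentration, mg/kg shrimp.
#' @param ir Shrimp intake rate, kg/day.
#' @param bw Body weight, kg.
#' @param ed Exposure duration, years.
#' @param osf Oral slope factor, (mg/kg/day)^-1 (default 7.3, benzo[a]pyrene).
#' @param lifespan_days Averaging time, days (default 28470 = 78 x 365).
#' @param days_per_year Exposure days per year (default 365).
#' @return Lifetime excess cancer risk (dimensionless).
#' @export
#' @examples
#' cancer_risk_point(6.68e-4, 0.0452, 63, 5)  # 2.2e-7
cancer_risk_point <- function(bap_eq, ir, bw, ed, osf = 7.3,
                              lifespan_days = 28470, days_per_year = 365) {
  if (any(bap_eq < 0) || any(ir < 0)) {
    stop("validation error: concentration and intake must be nonnegative")
  }
  if (any(bw <= 0)) stop("validation error: body weight must be positive")
  if (any(osf <= 0) || any(lifespan_days <= 0) || any(days_per_year <= 0)) {
    stop("validation error: slope factor, lifespan and days/year must be positive")
  }
  if (any(ed < 0) || any(ed * days_per_year > lifespan_days)) {
    stop("validation error: exposure duration must lie in [0, lifespan]")
  }
  (bap_eq * ir * days_per_year * ed) / (bw * lifespan_days) * osf
}

#' Configuration for the probabilistic cancer risk model
#'
#' @param bap_eq BaP-equivalent concentration, mg/kg shrimp (note ug/kg x
#'   1e-3; the ng/g values from [bap_equivalents()] are ug/kg).
#' @param ir_dist [fitted_dist()] of intake rate in g/day; converted to
#'   kg/day once, here at config construction.
#' @param bw_dist [fitted_dist()] of body weight, kg; a truncation of
#'   (0, 250) kg is applied if none is set.
#' @param ed_min,ed_max Exposure-duration uniform bounds, years (default
#'   5-10).
#' @param osf Oral slope factor, (mg/kg/day)^-1 (default 7.3).
#' @param lifespan_days Averaging time, days (default 28470).
#' @param days_per_year Exposure days per year (default 365).
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed Integer seed.
#' @return A validated `cancer_model_config` list. Intake-rate draws are
#'   divided by 1000 (g/day to kg/day) once, inside the simulation engine, so
#'   the risk equation consumes kg/day as written.
#' @export
cancer_model_config <- function(bap_eq, ir_dist, bw_dist,
                                ed_min = 5, ed_max = 10, osf = 7.3,
                                lifespan_days = 28470, days_per_year = 365,
                                n_iter = 10000L, seed = 1L) {
  stopifnot(is.numeric(bap_eq), bap_eq >= 0,
            inherits(ir_dist, "fitted_dist"), inherits(bw_dist, "fitted_dist"))
  check_positive_scalar(osf, "osf")
  check_positive_scalar(lifespan_days, "lifespan_days")
  check_positive_scalar(days_per_year, "days_per_year")
  if (!(ed_min >= 0 && ed_min <= ed_max)) {
    stop("configuration error: need 0 <= ed_min <= ed_max")
  }
  if (ed_max * days_per_year > lifespan_days) {
    stop("configuration error: exposure duration exceeds the averaging lifespan")
  }
  if (n_iter < 1) stop("configuration error: n_iter must be >= 1")
  if (is.null(bw_dist$truncation) && bw_dist$family != "point") {
    bw_dist <- truncate_dist(bw_dist, 0, 250)
  }
  structure(
    list(bap_eq = bap_eq, ir_dist = ir_dist,
         bw_dist = bw_dist, ed_min = ed_min, ed_max = ed_max, osf = osf,
         lifespan_days = lifespan_days, days_per_year = days_per_year,
         n_iter = as.integer(n_iter), seed = as.integer(seed)),
    class = "cancer_model_config"
  )
}

# shared exposure-factor draws (intake kg/day, body weight, exposure years)
cancer_draws <- function(config) {
  with_seed(config$seed, {
    ir_kg <- sample_dist(config$ir_dist, config$n_iter) / 1000
    bw <- sample_dist(config$bw_dist, config$n_iter)
    ed <- if (config$ed_min == config$ed_max) rep(config$ed_min, config$n_iter)
          else stats::runif(config$n_iter, config$ed_min, config$ed_max)
    if (any(bw <= 0)) {
      stop("internal error: body-weight draw <= 0 despite truncation contract")
    }
    list(ir_kg = ir_kg, bw = bw, ed = ed)
  })
}

# bap_eq-independent factor of the risk equation, so tier comparisons can
# reuse common random numbers
cancer_risk_factor_draws <- function(config) {
  d <- cancer_draws(config)
  (d$ir_kg * config$days_per_year * d$ed) /
    (d$bw * config$lifespan_days) * config$osf
}

#' Monte Carlo lifetime excess cancer risk distribution
#'
#' Per iteration draws intake rate, body weight and exposure duration
#' independently, evaluates the slope-factor risk equation and summarises the
#' resulting distribution. Deterministic given the config seed.
#'
#' @param config A [cancer_model_config()].
#' @param bins Histogram bin count (default 50).
#' @return A [summarize_distribution()] summary of the risk draws, with the
#'   iteration count attached.
#' @export
cancer_risk_monte_carlo <- function(config, bins = 50L) {
  stopifnot(inherits(config, "cancer_model_config"))
  d <- cancer_draws(config)
  risk <- cancer_risk_point(config$bap_eq, d$ir_kg, d$bw, d$ed, config$osf,
                            config$lifespan_days, config$days_per_year)
  summarize_distribution(risk, bins = bins)
}

#' Tiered cancer-risk analysis under common random numbers
#'
#' Computes the per-tier BaP-equivalent concentration from a censored
#' chemistry table (conservative convention: analytes lacking an accepted RPF
#' get `default_rpf`, by default BaP's own potency of 1) and evaluates the
#' Monte Carlo risk distribution for each tier with the same draw sequence,
#' so per-tier risks are exactly proportional to the tier BaPeq totals.
#'
#' @param concentrations Uncensored concentration table, ng/g (run
#'   [substitute_nondetects()] first), or `NULL` when `tier_bap_eq` is given.
#' @param meta Analyte metadata (required with `concentrations`).
#' @param config A [cancer_model_config()]; its `bap_eq` field is ignored in
#'   favour of the per-tier totals.
#' @param tiers Character vector of tiers, see [expand_analyte_tier()].
#' @param default_rpf Potency for analytes lacking an RPF in the expanded
#'   tiers (default 1); the `cpah7` tier always uses accepted RPFs only.
#' @param tier_bap_eq Optional named numeric vector of tier BaPeq totals in
#'   mg/kg, bypassing the chemistry computation.
#' @param bins Histogram bin count.
#' @return Tibble with one row per tier: `tier`, `bap_eq_mg_per_kg`, `mean`,
#'   `sd`, `p95`, `p99`, and a list column `summary` of full
#'   [summarize_distribution()] objects.
#' @export
tiered_risk_analysis <- function(concentrations = NULL, meta = NULL, config,
                                 tiers = c("cpah7", "plus_unsubstituted",
                                           "plus_alkylated"),
                                 default_rpf = 1, tier_bap_eq = NULL,
                                 bins = 50L) {
  stopifnot(inherits(config, "cancer_model_config"))
  if (length(tiers) < 1L && is.null(tier_bap_eq)) {
    stop("tiered_risk_analysis requires at least one tier")
  }
  if (is.null(tier_bap_eq)) {
    if (is.null(concentrations) || is.null(meta)) {
      stop("supply either a concentration table with metadata or 'tier_bap_eq'")
    }
    tier_bap_eq <- vapply(tiers, function(t) {
      per_sample <- bap_equivalents(
        concentrations, meta, tier = t,
        default_rpf = if (t == "cpah7") NULL else default_rpf
      )
      mean(per_sample$bap_eq_ug_per_kg) * 1e-3  # ug/kg -> mg/kg
    }, 0)
  }
  if (length(tier_bap_eq) < 1L) stop("empty tier list")
  factors <- cancer_risk_factor_draws(config)
  rows <- lapply(seq_along(tier_bap_eq), function(i) {
    s <- summarize_distribution(tier_bap_eq[[i]] * factors, bins = bins)
    tibble::tibble(tier = names(tier_bap_eq)[i],
                   bap_eq_mg_per_kg = tier_bap_eq[[i]],
                   mean = s$mean, sd = s$sd, p95 = s$p95, p99 = s$p99,
                   summary = list(s))
  })
  dplyr::bind_rows(rows)
}
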