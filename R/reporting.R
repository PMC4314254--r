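#' Summarise a Monte Carlo output distribution
#'
#' Mean, SD, percentiles (linear interpolation on order statistics, the
#' default type-7 estimator) and a relative-frequency histogram whose bar
#' heights sum to 1. Binning uses equal-width bins from 0 (or the sample
#' minimum, if negative values are present) to the 99.9th percentile, plus a
#' final overflow bin to the maximum so no draw is dropped.
#'
#' @param samples Numeric vector (>= 1 value).
#' @param bins Number of equal-width bins (default 50).
#' @return A list of class `risk_summary`: `mean`, `sd`, `p5`, `p50`, `p95`,
#'   `p99`, `n`, and `histogram` (tibble `bin_left`, `bin_right`,
#'   `rel_freq`).
#' @export
#' @examples
#' summarize_distribution(1:100)$p50  # 50.5
summarize_distribution <- function(samples, bins = 50L) {
  if (length(samples) < 1L || anyNA(samples)) {
    stop("summarize_distribution requires at least one non-missing sample")
  }
  stopifnot(bins >= 1)
  qs <- stats::quantile(samples, c(0.05, 0.5, 0.95, 0.99, 0.999), type = 7)
  lo <- min(0, min(samples))
  hi <- unname(qs[5])
  mx <- max(samples)
  if (hi <= lo) hi <- mx           # (near-)degenerate samples
  if (mx <= lo) { lo <- mx - 1; hi <- mx }  # all-constant at/below zero
  edges <- seq(lo, hi, length.out = bins + 1L)
  if (mx > hi) edges <- c(edges, mx)
  counts <- graphics::hist(samples, breaks = edges, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  structure(
    list(
      mean = mean(samples),
      sd = if (length(samples) > 1L) stats::sd(samples) else 0,
      p5 = unname(qs[1]), p50 = unname(qs[2]),
      p95 = unname(qs[3]), p99 = unname(qs[4]),
      n = length(samples),
      histogram = tibble::tibble(
        bin_left = edges[-length(edges)],
        bin_right = edges[-1],
        rel_freq = counts / length(samples)
      )
    ),
    class = "risk_summary"
  )
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf(
    "<risk_summary> n=%d  mean=%.4g  sd=%.4g  p5=%.4g  p50=%.4g  p95=%.4g  p99=%.4g\n",
    x$n, x$mean, x$sd, x$p5, x$p50, x$p95, x$p99))
  invisible(x)
}

#' Assessment run configuration
#'
#' Bundles every knob of the end-to-end pipeline. Inputs are either paths to
#' survey/chemistry CSVs or synthetic-generator configurations (exactly one
#' per input kind).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; the survey and chemistry generator seeds are
#'   derived from it deterministically so each table has its own stream.
#' @param n_iter Monte Carlo iterations.
#' @param survey Either a CSV path or a [survey_gen_config()]; `NULL` means
#'   a default synthetic survey under the derived seed.
#' @param chemistry Either a CSV path or a [chem_gen_config()]; `NULL` means
#'   a default synthetic chemistry table under the derived seed.
#' @param meta_path Analyte metadata CSV (default: packaged table).
#' @param size_table Size-class conversion table (default
#'   [default_size_table()]).
#' @param tiers Analyte tiers for the cancer assessment.
#' @param ed_min,ed_max,osf,lifespan_days,days_per_year Cancer-model
#'   constants, see [cancer_model_config()].
#' @param report_digits Significant figures for the human-readable tables.
#' @return A validated `assessment_config` list.
#' @export
assessment_config <- function(out_dir, seed = 1L, n_iter = 10000L,
                              survey = NULL, chemistry = NULL,
                              meta_path = NULL, size_table = default_size_table(),
                              tiers = c("cpah7", "plus_unsubstituted",
                                        "plus_alkylated"),
                              ed_min = 5, ed_max = 10, osf = 7.3,
                              lifespan_days = 28470, days_per_year = 365,
                              report_digits = 2L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  seed <- as.integer(seed)
  if (is.null(survey)) {
    survey <- survey_gen_config(n_respondents = 115, seed = seed * 2L + 1L)
  }
  if (is.null(chemistry)) {
    chemistry <- chem_gen_config(seed = seed * 2L + 2L)
  }
  structure(
    list(out_dir = out_dir, seed = seed, n_iter = as.integer(n_iter),
         survey = survey, chemistry = chemistry, meta_path = meta_path,
         size_table = size_table, tiers = tiers, ed_min = ed_min,
         ed_max = ed_max, osf = osf, lifespan_days = lifespan_days,
         days_per_year = days_per_year,
         report_digits = as.integer(report_digits)),
    class = "assessment_config"
  )
}

read_survey_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("survey CSV not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    sex = readr::col_character(),
    body_weight_kg = readr::col_double(),
    shrimp_per_meal = readr::col_double(),
    meals_per_week = readr::col_double(),
    size_class = readr::col_character()
  ), progress = FALSE)
}

read_chemistry_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("chemistry CSV not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    analyte = readr::col_character(),
    value = readr::col_double(),
    nondetect = readr::col_logical(),
    lod_ng_per_g = readr::col_double()
  ), progress = FALSE)
}

#' Run the full risk-assessment pipeline
#'
#' Executes, in order: input acquisition (synthetic generation or CSV read),
#' intake-rate computation, exposure-factor distribution fitting and ranking
#' (body weight: normal / log-normal / Pearson V, truncated to (0, 250) kg;
#' intake: Weibull / log-normal / Pearson VI), nondetect substitution, parent
#' totals, deterministic and Monte Carlo hazard quotients, and the tiered
#' Monte Carlo cancer-risk analysis. Writes `hq_table.csv`,
#' `cancer_risk_tiers.csv`, `distribution_fits.json`, per-tier histogram
#' CSVs and a JSON run manifest into `config$out_dir`.
#'
#' @param config An [assessment_config()].
#' @return Invisibly, a list with the in-memory results (`intake`, `fits`,
#'   `hq_table`, `hq_mc`, `cancer`, `manifest`).
#' @export
run_assessment <- function(config) {
  stopifnot(inherits(config, "assessment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)  # leave no partial outputs behind
    stop(sprintf("assessment stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # inputs
  survey <- tryCatch(
    if (inherits(config$survey, "survey_gen_config"))
      generate_survey(config$survey) else read_survey_csv(config$survey),
    error = function(e) on_fail("survey input", e))
  meta <- tryCatch(
    if (is.null(config$meta_path)) load_analyte_meta()
    else load_analyte_meta(config$meta_path),
    error = function(e) on_fail("analyte metadata", e))
  chem <- tryCatch(
    if (inherits(config$chemistry, "chem_gen_config"))
      generate_chemistry(config$chemistry, meta)
    else read_chemistry_csv(config$chemistry),
    error = function(e) on_fail("chemistry input", e))

  # intake rates
  intake <- tryCatch(intake_table(survey, config$size_table),
                     error = function(e) on_fail("intake", e))

  # distribution fitting
  fits <- tryCatch({
    bw_rank <- rank_fits(survey$body_weight_kg, c("normal", "lognormal", "pearson5"))
    ir_pos <- intake$rates$intake_g_per_day[intake$rates$intake_g_per_day > 0]
    ir_rank <- rank_fits(ir_pos, c("weibull", "lognormal", "pearson6"))
    list(bw_rank = bw_rank, ir_rank = ir_rank,
         bw = truncate_dist(best_fit(bw_rank), 0, 250),
         ir = best_fit(ir_rank))
  }, error = function(e) on_fail("distribution fitting", e))

  # chemistry
  chem_sub <- tryCatch(substitute_nondetects(chem),
                       error = function(e) on_fail("nondetect substitution", e))
  parents <- tryCatch(parent_totals(chem_sub, meta),
                      error = function(e) on_fail("parent totals", e))

  # noncancer risk
  hq <- tryCatch({
    levels <- dplyr::summarise(
      dplyr::group_by(parents, .data$parent),
      rfd_mg_per_kg_day = .data$rfd_mg_per_kg_day[1],
      level_ppm = mean(.data$total_ng_per_g) * 1e-3,
      .groups = "drop"
    )
    levels <- dplyr::rename(levels, analyte = "parent")
    pt <- hq_point_table(
      levels,
      ir_values = c(mean = intake$summary$mean, p95 = intake$summary$p95),
      bw = mean(survey$body_weight_kg)
    )
    mc <- lapply(stats::setNames(seq_len(nrow(levels)), levels$analyte), function(i) {
      conc <- parents$total_ng_per_g[parents$parent == levels$analyte[i]] * 1e-3
      # a fully censored parent has constant substituted values: model it as
      # the fixed level rather than a zero-variance log-normal
      cd <- if (stats::sd(conc) < 1e-12 * max(conc)) point_dist(mean(conc))
            else fit_mle(conc, "lognormal")
      hq_monte_carlo(cd, fits$ir, fits$bw, levels$rfd_mg_per_kg_day[i],
                     n_iter = config$n_iter, seed = config$seed + i)
    })
    list(point = pt, mc = mc, levels = levels)
  }, error = function(e) on_fail("noncancer risk", e))

  # cancer risk
  cancer <- tryCatch({
    cfg <- cancer_model_config(
      bap_eq = 0,  # per-tier totals supplied by tiered_risk_analysis
      ir_dist = fits$ir, bw_dist = fits$bw,
      ed_min = config$ed_min, ed_max = config$ed_max, osf = config$osf,
      lifespan_days = config$lifespan_days,
      days_per_year = config$days_per_year,
      n_iter = config$n_iter, seed = config$seed
    )
    tiered_risk_analysis(chem_sub, meta, cfg, tiers = config$tiers)
  }, error = function(e) on_fail("cancer risk", e))

  # outputs
  tryCatch({
    d <- config$report_digits
    t1 <- hq$point
    t1$adi_mg_per_kg_day <- signif(t1$adi_mg_per_kg_day, d)
    t1$hq <- signif(t1$hq, d)
    p1 <- file.path(config$out_dir, "hq_table.csv")
    readr::write_csv(t1, p1); written <- c(written, p1)

    t2 <- cancer[, c("tier", "bap_eq_mg_per_kg", "mean", "sd", "p95", "p99")]
    p2 <- file.path(config$out_dir, "cancer_risk_tiers.csv")
    readr::write_csv(t2, p2); written <- c(written, p2)

    for (i in seq_len(nrow(cancer))) {
      ph <- file.path(config$out_dir,
                      sprintf("histogram_%s.csv", cancer$tier[i]))
      readr::write_csv(cancer$summary[[i]]$histogram, ph)
      written <- c(written, ph)
    }

    pf <- file.path(config$out_dir, "distribution_fits.json")
    writeLines(jsonlite::toJSON(list(
      body_weight = jsonlite::fromJSON(dist_to_json(fits$bw)),
      intake_rate = jsonlite::fromJSON(dist_to_json(fits$ir)),
      body_weight_ranking = fits$bw_rank$table,
      intake_rate_ranking = fits$ir_rank$table
    ), auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE), pf)
    written <- c(written, pf)

    manifest <- list(
      package = "shrimppahr",
      version = as.character(utils::packageVersion("shrimppahr")),
      seed = config$seed, n_iter = config$n_iter, tiers = config$tiers,
      counts = list(
        respondents = nrow(survey),
        chemistry_records = nrow(chem),
        nondetects_substituted = sum(chem$nondetect),
        iterations = config$n_iter
      ),
      config = list(
        ed_min = config$ed_min, ed_max = config$ed_max, osf = config$osf,
        lifespan_days = config$lifespan_days,
        days_per_year = config$days_per_year,
        synthetic_survey = inherits(config$survey, "survey_gen_config"),
        synthetic_chemistry = inherits(config$chemistry, "chem_gen_config")
      )
    )
    pm <- file.path(config$out_dir, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), pm)
    written <- c(written, pm)
  }, error = function(e) on_fail("report writing", e))

  message(sprintf(
    "assessment complete: %d respondents, %d chemistry records (%d nondetects substituted), %d iterations",
    nrow(survey), nrow(chem), sum(chem$nondetect), config$n_iter))
  invisible(list(intake = intake, fits = fits, hq_table = hq$point,
                 hq_mc = hq$mc, cancer = cancer,
                 files = written))
}
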