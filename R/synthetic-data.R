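#' Default category tables for the synthetic survey generator
#'
#' Weekly meal-frequency, shrimp-per-meal and size-class categories with their
#' default probabilities. The defaults are calibrated so that the implied mean
#' intake rate sits near 45 g/day for a population eating shrimp several times
#' a week, mostly 10-15 medium-to-large shrimp per meal, with sex-specific
#' mean body weights of 67.5 and 58.9 kg averaging about 63 kg. Category
#' ranges are resolved to their midpoints.
#'
#' @name survey_defaults
NULL

default_meal_freq <- function() {
  c("less than weekly" = 0.25, "once per week" = 1, "twice per week" = 2,
    "several times per week" = 3, "most days" = 5, "daily" = 7)
}
default_meal_freq_pmf <- function() {
  c(0.15, 0.20, 0.25, 0.30, 0.08, 0.02)
}

default_shrimp_per_meal <- function() {
  c("1-5" = 3, "5-10" = 7.5, "10-15" = 12.5, "15-20" = 17.5, "20+" = 22.5)
}
default_shrimp_per_meal_pmf <- function() {
  c(0.10, 0.20, 0.40, 0.20, 0.10)
}

default_size_class_pmf <- function() {
  c(small = 0.10, medium = 0.40, large = 0.40, extra_large = 0.10)
}

#' Configuration for the synthetic survey generator
#'
#' Body weights are drawn from sex-specific normal distributions truncated to
#' (30, 250) kg; consumption pattern fields are drawn from categorical PMFs.
#' Defaults emulate a shrimp-consumer survey population with mean body weight
#' near 63 kg (67.5 kg male, 58.9 kg female), modal consumption several times
#' per week and a modal meal of 10-15 shrimp.
#'
#' @param n_respondents Number of respondents to generate (>= 1).
#' @param seed Integer RNG seed for this table.
#' @param bw_mean_male,bw_mean_female Sex-specific mean body weights, kg.
#' @param bw_sd Body-weight SD, kg (shared across sexes); a calibration knob,
#'   since surveys of this kind report means only.
#' @param bw_bounds Truncation interval for generated body weights, kg.
#' @param meal_freq Named numeric vector mapping frequency category labels to
#'   meals/week values.
#' @param meal_freq_pmf Probability vector over `meal_freq` categories.
#' @param shrimp_per_meal Named numeric vector mapping portion category labels
#'   to shrimp-per-meal counts (range midpoints).
#' @param shrimp_per_meal_pmf Probability vector over portion categories.
#' @param size_class_pmf Named probability vector over size classes.
#' @return A validated `survey_gen_config` list.
#' @export
survey_gen_config <- function(n_respondents = 115,
                              seed = 1L,
                              bw_mean_male = 67.5,
                              bw_mean_female = 58.9,
                              bw_sd = 11.0,
                              bw_bounds = c(30, 250),
                              meal_freq = default_meal_freq(),
                              meal_freq_pmf = default_meal_freq_pmf(),
                              shrimp_per_meal = default_shrimp_per_meal(),
                              shrimp_per_meal_pmf = default_shrimp_per_meal_pmf(),
                              size_class_pmf = default_size_class_pmf()) {
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop("configuration error: 'n_respondents' must be >= 1")
  }
  check_positive_scalar(bw_mean_male, "bw_mean_male")
  check_positive_scalar(bw_mean_female, "bw_mean_female")
  check_positive_scalar(bw_sd, "bw_sd")
  stopifnot(length(bw_bounds) == 2L, bw_bounds[1] < bw_bounds[2])
  check_pmf(meal_freq_pmf, "meal_freq_pmf")
  check_pmf(shrimp_per_meal_pmf, "shrimp_per_meal_pmf")
  check_pmf(size_class_pmf, "size_class_pmf")
  if (length(meal_freq_pmf) != length(meal_freq)) {
    stop("configuration error: 'meal_freq_pmf' length must match 'meal_freq'")
  }
  if (length(shrimp_per_meal_pmf) != length(shrimp_per_meal)) {
    stop("configuration error: 'shrimp_per_meal_pmf' length must match 'shrimp_per_meal'")
  }
  if (is.null(names(size_class_pmf))) {
    stop("configuration error: 'size_class_pmf' must be named by size class")
  }
  structure(
    list(n_respondents = as.integer(n_respondents), seed = as.integer(seed),
         bw_mean_male = bw_mean_male, bw_mean_female = bw_mean_female,
         bw_sd = bw_sd, bw_bounds = as.numeric(bw_bounds),
         meal_freq = meal_freq, meal_freq_pmf = meal_freq_pmf,
         shrimp_per_meal = shrimp_per_meal,
         shrimp_per_meal_pmf = shrimp_per_meal_pmf,
         size_class_pmf = size_class_pmf),
    class = "survey_gen_config"
  )
}

# truncated-normal draws by inversion on the restricted quantile range
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic survey-response table
#'
#' One row per respondent: sex (even split in expectation), body weight from
#' the sex-specific truncated normal, and consumption-pattern categories from
#' the configured PMFs. Deterministic given `config$seed`.
#'
#' @param config A [survey_gen_config()].
#' @return Tibble with columns `respondent_id`, `sex`, `body_weight_kg`,
#'   `shrimp_per_meal`, `meals_per_week`, `size_class`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_gen_config"))
  n <- config$n_respondents
  with_seed(config$seed, {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    mu <- ifelse(sex == "male", config$bw_mean_male, config$bw_mean_female)
    bw <- rnorm_trunc(n, mu, config$bw_sd,
                      config$bw_bounds[1], config$bw_bounds[2])
    freq_idx <- sample.int(length(config$meal_freq), n, replace = TRUE,
                           prob = config$meal_freq_pmf)
    meal_idx <- sample.int(length(config$shrimp_per_meal), n, replace = TRUE,
                           prob = config$shrimp_per_meal_pmf)
    size <- sample(names(config$size_class_pmf), n, replace = TRUE,
                   prob = config$size_class_pmf)
    tibble::tibble(
      respondent_id = sprintf("R%04d", seq_len(n)),
      sex = sex,
      body_weight_kg = bw,
      shrimp_per_meal = unname(config$shrimp_per_meal[meal_idx]),
      meals_per_week = unname(config$meal_freq[freq_idx]),
      size_class = size
    )
  })
}

#' Default per-analyte concentration settings for the chemistry generator
#'
#' Geometric mean (ng/g wet weight), geometric SD and detection probability
#' for the analytes treated as detectable; every analyte in the metadata that
#' is not listed here is generated as a pure nondetect. Levels are all below
#' 2 ng/g, matching the magnitude of PAHs seen in lightly contaminated shrimp
#' tissue.
#'
#' @return Tibble with columns `analyte`, `geo_mean`, `geo_sd`, `p_detect`.
#' @export
default_chem_levels <- function() {
  tibble::tribble(
    ~analyte,               ~geo_mean, ~geo_sd, ~p_detect,
    "naphthalene",               1.60,    1.5,      0.90,
    "2-methylnaphthalene",       1.20,    1.5,      0.90,
    "biphenyl",                  0.35,    1.4,      0.80,
    "dibenzofuran",              0.30,    1.4,      0.80,
    "phenanthrene",              0.55,    1.5,      0.85,
    "1-methylphenanthrene",      0.30,    1.4,      0.70,
    "pyrene",                    0.50,    1.5,      0.85,
    "perylene",                  0.25,    1.4,      0.70
  )
}

#' Configuration for the synthetic shrimp-chemistry generator
#'
#' @param seed Integer RNG seed for this table.
#' @param levels Tibble as [default_chem_levels()]: per-analyte geometric mean
#'   (ng/g), geometric SD (> 1 allowed; must be > 0) and detection
#'   probability in `[0, 1]`.
#' @param n_samples Number of composite samples (default 24: eight nettings
#'   with three composites each).
#' @return A validated `chem_gen_config` list.
#' @export
chem_gen_config <- function(seed = 1L, levels = default_chem_levels(),
                            n_samples = 24L) {
  stopifnot(is.data.frame(levels),
            all(c("analyte", "geo_mean", "geo_sd", "p_detect") %in% names(levels)))
  if (any(levels$geo_mean <= 0) || any(levels$geo_sd <= 0)) {
    stop("configuration error: 'geo_mean' and 'geo_sd' must be strictly positive")
  }
  if (any(levels$p_detect < 0 | levels$p_detect > 1)) {
    stop("configuration error: 'p_detect' must lie in [0, 1]")
  }
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("configuration error: 'n_samples' must be >= 1")
  }
  structure(
    list(seed = as.integer(seed), levels = tibble::as_tibble(levels),
         n_samples = as.integer(n_samples)),
    class = "chem_gen_config"
  )
}

#' Generate a synthetic shrimp-chemistry table
#'
#' Emits one record per composite sample and metadata analyte. A configured
#' analyte is detected with its detection probability, in which case a
#' concentration is drawn log-normally from its geometric mean and geometric
#' SD; otherwise (and for every analyte absent from the level configuration)
#' the record is a nondetect carrying the analyte's LOD from the metadata.
#' Deterministic given `config$seed`.
#'
#' @param config A [chem_gen_config()].
#' @param meta Analyte metadata table, see [load_analyte_meta()].
#' @return Tibble with columns `sample_id`, `analyte`, `value` (ng/g wet
#'   weight; `NA` for nondetects), `nondetect` (logical), `lod_ng_per_g`.
#' @export
generate_chemistry <- function(config, meta) {
  stopifnot(inherits(config, "chem_gen_config"))
  check_analyte_meta(meta)
  unknown <- setdiff(config$levels$analyte, meta$analyte)
  if (length(unknown) > 0L) {
    stop(sprintf("configured analytes missing from metadata: %s",
                 paste(unknown, collapse = ", ")))
  }
  grid <- expand.grid(sample_id = sprintf("S%03d", seq_len(config$n_samples)),
                      analyte = meta$analyte, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$analyte), , drop = FALSE]
  lv <- config$levels[match(grid$analyte, config$levels$analyte), ]
  p_det <- ifelse(is.na(lv$p_detect), 0, lv$p_detect)
  lod <- meta$lod_ng_per_g[match(grid$analyte, meta$analyte)]
  with_seed(config$seed, {
    detected <- stats::runif(nrow(grid)) < p_det
    value <- rep(NA_real_, nrow(grid))
    if (any(detected)) {
      value[detected] <- stats::rlnorm(sum(detected),
                                       meanlog = log(lv$geo_mean[detected]),
                                       sdlog = log(lv$geo_sd[detected]))
    }
    tibble::tibble(
      sample_id = grid$sample_id,
      analyte = grid$analyte,
      value = value,
      nondetect = !detected,
      lod_ng_per_g = lod
    )
  })
}
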