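#' Average daily intake of a contaminant from shrimp consumption
#'
#' ADI (mg/kg body weight/day) = concentration (ppm, i.e. mg contaminant per
#' kg shrimp) x intake rate (g shrimp/day) / (body weight (kg) x CF), with CF
#' the 1,000 g/kg mass conversion.
#'
#' @param conc_ppm Contaminant concentration, mg/kg shrimp (ppm). Note
#'   1 ng/g wet weight = 1 ug/kg = 1e-3 ppm.
#' @param ir Shrimp intake rate, g/day.
#' @param bw Body weight, kg (> 0).
#' @param cf Conversion factor, g shrimp per kg shrimp (default 1000).
#' @return Average daily intake, mg/kg-day.
#' @export
#' @examples
#' average_daily_intake(4.9e-3, 45.2, 63)  # 3.52e-6 mg/kg-day
average_daily_intake <- function(conc_ppm, ir, bw, cf = 1000) {
  if (any(conc_ppm < 0) || any(ir < 0)) {
    stop("validation error: concentration and intake rate must be nonnegative")
  }
  if (any(bw <= 0)) stop("validation error: body weight must be positive")
  if (any(cf <= 0)) stop("validation error: conversion factor must be positive")
  conc_ppm * ir / (bw * cf)
}

#' Noncancer hazard quotient
#'
#' HQ = average daily intake / reference dose. HQ > 1 flags a potential
#' noncancer health concern.
#'
#' @param adi Average daily intake, mg/kg-day (>= 0).
#' @param rfd Oral reference dose, mg/kg-day (> 0).
#' @return Numeric HQ with attribute `exceeds` (logical, HQ > 1 anywhere).
#' @export
hazard_quotient <- function(adi, rfd) {
  if (any(rfd <= 0)) stop("validation error: reference dose must be positive")
  if (any(adi < 0)) stop("validation error: daily intake must be nonnegative")
  hq <- adi / rfd
  attr(hq, "exceeds") <- any(hq > 1)
  hq
}

#' Deterministic hazard-quotient table at mean and upper-bound consumption
#'
#' One row per analyte and consumption variant, evaluating the ADI and HQ at
#' fixed exposure factors. Analytes without an RfD are skipped with a warning.
#'
#' @param levels Data frame with columns `analyte`, `level_ppm` (mg/kg
#'   shrimp) and `rfd_mg_per_kg_day`.
#' @param ir_values Named numeric vector of intake-rate variants, g/day
#'   (e.g. `c(mean = 45.2, p95 = 57.5)`).
#' @param bw Body weight, kg.
#' @param cf Conversion factor, g/kg (default 1000).
#' @return Tibble `analyte`, `rfd_mg_per_kg_day`, `level_ppm`, `variant`,
#'   `ir_g_per_day`, `adi_mg_per_kg_day`, `hq`.
#' @export
hq_point_table <- function(levels, ir_values, bw, cf = 1000) {
  stopifnot(is.data.frame(levels),
            all(c("analyte", "level_ppm", "rfd_mg_per_kg_day") %in% names(levels)))
  if (is.null(names(ir_values)) || any(!nzchar(names(ir_values)))) {
    stop("'ir_values' must be a named vector of consumption variants")
  }
  no_rfd <- is.na(levels$rfd_mg_per_kg_day)
  if (any(no_rfd)) {
    warning(sprintf("skipping analyte(s) without an RfD: %s",
                    paste(levels$analyte[no_rfd], collapse = ", ")))
    levels <- levels[!no_rfd, , drop = FALSE]
  }
  if (nrow(levels) == 0L) {
    return(tibble::tibble(analyte = character(), rfd_mg_per_kg_day = double(),
                          level_ppm = double(), variant = character(),
                          ir_g_per_day = double(), adi_mg_per_kg_day = double(),
                          hq = double()))
  }
  grid <- expand.grid(i = seq_len(nrow(levels)), v = seq_along(ir_values))
  adi <- average_daily_intake(levels$level_ppm[grid$i], ir_values[grid$v], bw, cf)
  tibble::tibble(
    analyte = levels$analyte[grid$i],
    rfd_mg_per_kg_day = levels$rfd_mg_per_kg_day[grid$i],
    level_ppm = levels$level_ppm[grid$i],
    variant = names(ir_values)[grid$v],
    ir_g_per_day = unname(ir_values[grid$v]),
    adi_mg_per_kg_day = adi,
    hq = adi / levels$rfd_mg_per_kg_day[grid$i]
  )
}

#' Monte Carlo hazard-quotient distribution for one analyte
#'
#' Per iteration, draws concentration (ppm), intake rate (g/day) and body
#' weight (kg) independently from their fitted distributions, evaluates the
#' ADI and HQ, and summarises the resulting distribution. Deterministic given
#' `seed`.
#'
#' @param conc_dist [fitted_dist()] of the analyte concentration, ppm
#'   (mg/kg shrimp).
#' @param ir_dist [fitted_dist()] of the intake rate, g/day.
#' @param bw_dist [fitted_dist()] of body weight, kg (truncate to plausible
#'   bounds with [truncate_dist()]).
#' @param rfd Oral reference dose, mg/kg-day.
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed.
#' @param cf Conversion factor, g/kg (default 1000).
#' @param bins Histogram bin count for the summary (default 50).
#' @return A [summarize_distribution()] summary of the HQ draws.
#' @export
hq_monte_carlo <- function(conc_dist, ir_dist, bw_dist, rfd, n_iter = 10000L,
                           seed = 1L, cf = 1000, bins = 50L) {
  stopifnot(inherits(conc_dist, "fitted_dist"), inherits(ir_dist, "fitted_dist"),
            inherits(bw_dist, "fitted_dist"), n_iter >= 1)
  check_positive_scalar(rfd, "rfd")
  draws <- with_seed(seed, {
    conc <- sample_dist(conc_dist, n_iter)
    ir <- sample_dist(ir_dist, n_iter)
    bw <- sample_dist(bw_dist, n_iter)
    if (any(bw <= 0)) {
      stop("internal error: body-weight draw <= 0 despite truncation contract")
    }
    hazard_quotient(average_daily_intake(conc, ir, bw, cf), rfd)
  })
  summarize_distribution(as.numeric(draws), bins = bins)
}
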