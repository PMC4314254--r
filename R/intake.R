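#' Default shrimp size-to-mass conversion table
#'
#' U.S. commercial shrimp size classes are labelled by count per pound; the
#' grams-per-shrimp conversion uses the midpoint of each count range and
#' 453.592 g/lb (e.g. medium, 41-50 per lb, midpoint 45.5 -> 9.97 g/shrimp).
#' Override with any table carrying the same columns to substitute a
#' survey-specific conversion.
#'
#' @return Tibble with columns `size_class`, `count_per_lb_mid`,
#'   `grams_per_shrimp`.
#' @export
default_size_table <- function() {
  tab <- tibble::tribble(
    ~size_class,   ~count_per_lb_mid,
    "small",                    55.5,  # 51-60 per lb
    "medium",                   45.5,  # 41-50 per lb
    "large",                    35.5,  # 31-40 per lb
    "extra_large",              28.0   # 26-30 per lb
  )
  tab$grams_per_shrimp <- 453.592 / tab$count_per_lb_mid
  tab
}

#' Grams of shrimp per individual by commercial size class
#'
#' @param size_class Character vector of size-class labels.
#' @param table Conversion table with columns `size_class` and
#'   `grams_per_shrimp` (default [default_size_table()]).
#' @return Numeric vector of grams per shrimp.
#' @export
#' @examples
#' grams_per_shrimp("medium")  # 9.97 g
grams_per_shrimp <- function(size_class, table = default_size_table()) {
  stopifnot(is.data.frame(table),
            all(c("size_class", "grams_per_shrimp") %in% names(table)))
  if (any(table$grams_per_shrimp <= 0)) {
    stop("size conversion table must have strictly positive masses")
  }
  idx <- match(size_class, table$size_class)
  if (anyNA(idx)) {
    missing <- unique(size_class[is.na(idx)])
    stop(sprintf("size class(es) %s not in conversion table (available: %s)",
                 paste(sQuote(missing), collapse = ", "),
                 paste(sQuote(table$size_class), collapse = ", ")))
  }
  table$grams_per_shrimp[idx]
}

#' Daily shrimp intake rate for survey respondents
#'
#' Intake rate (g/day) = shrimp per meal x grams per shrimp x meals per week
#' / 7 days. Respondents reporting zero consumption get rate 0 and are
#' retained, so they dilute the population mean just as in the empirical
#' summary.
#'
#' @param records Data frame of survey records with columns
#'   `shrimp_per_meal`, `meals_per_week`, `size_class` (one or more rows).
#' @param table Size conversion table, see [grams_per_shrimp()].
#' @return Numeric vector of intake rates, g shrimp/day.
#' @export
#' @examples
#' intake_rate(data.frame(shrimp_per_meal = 12, meals_per_week = 3,
#'                        size_class = "medium"))
intake_rate <- function(records, table = default_size_table()) {
  stopifnot(is.data.frame(records),
            all(c("shrimp_per_meal", "meals_per_week", "size_class") %in% names(records)))
  if (any(records$shrimp_per_meal < 0) || any(records$meals_per_week < 0)) {
    stop("validation error: 'shrimp_per_meal' and 'meals_per_week' must be nonnegative")
  }
  g <- grams_per_shrimp(records$size_class, table)
  records$shrimp_per_meal * g * records$meals_per_week / 7
}

#' Per-respondent intake rates with population summary
#'
#' @param records Survey table (>= 1 row) with columns `respondent_id`,
#'   `shrimp_per_meal`, `meals_per_week`, `size_class`.
#' @param table Size conversion table.
#' @return A list: `rates`, a tibble (`respondent_id`, `intake_g_per_day`);
#'   `summary`, a list with `mean`, `sd` and the empirical 95th percentile
#'   `p95` (linear interpolation on order statistics).
#' @export
intake_table <- function(records, table = default_size_table()) {
  if (!is.data.frame(records) || nrow(records) < 1L) {
    stop("intake_table requires at least one survey record")
  }
  rates <- intake_rate(records, table)
  list(
    rates = tibble::tibble(
      respondent_id = if ("respondent_id" %in% names(records))
        records$respondent_id else sprintf("R%04d", seq_len(nrow(records))),
      intake_g_per_day = rates
    ),
    summary = list(
      mean = mean(rates),
      sd = if (length(rates) > 1L) stats::sd(rates) else 0,
      p95 = unname(stats::quantile(rates, 0.95, type = 7))
    )
  )
}
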