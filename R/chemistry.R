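#' Load the analyte metadata table
#'
#' Per-analyte regulatory constants: class (`cpah7` for the seven priority
#' carcinogenic PAHs, `unsubstituted`, or `alkylated`), the parent compound
#' for alkylated homologs, oral reference dose (mg/kg-day) where one is
#' accepted, relative potency factor (RPF, relative to benzo[a]pyrene) where
#' one is accepted, and the limit of detection (ng/g wet weight).
#'
#' The packaged default covers an 81-analyte petroleum-PAH panel. Its RPFs
#' are the U.S. EPA provisional relative potencies for the seven cPAHs; its
#' LODs are a synthetic calibration (per-analyte detection limits are
#' laboratory-specific and rarely published), chosen so that the fully
#' censored 7-cPAH panel yields a benzo[a]pyrene-equivalent concentration of
#' 0.668 ug/kg — a representative value for shrimp tissue in which no cPAH is
#' detected at sub-ng/g detection limits.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Tibble with columns `analyte`, `class`, `parent`,
#'   `rfd_mg_per_kg_day`, `rpf`, `lod_ng_per_g`.
#' @export
load_analyte_meta <- function(path = system.file("extdata", "analyte_meta.csv",
                                                 package = "shrimppahr")) {
  meta <- readr::read_csv(
    path,
    col_types = readr::cols(
      analyte = readr::col_character(),
      class = readr::col_character(),
      parent = readr::col_character(),
      rfd_mg_per_kg_day = readr::col_double(),
      rpf = readr::col_double(),
      lod_ng_per_g = readr::col_double()
    ),
    progress = FALSE
  )
  check_analyte_meta(meta)
  meta
}

check_analyte_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  required <- c("analyte", "class", "parent", "rfd_mg_per_kg_day", "rpf",
                "lod_ng_per_g")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop(sprintf("analyte metadata lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$analyte)) stop("duplicate analytes in metadata")
  bad_class <- setdiff(unique(meta$class), c("cpah7", "unsubstituted", "alkylated"))
  if (length(bad_class) > 0L) {
    stop(sprintf("unknown analyte class(es): %s", paste(bad_class, collapse = ", ")))
  }
  alk <- meta$class == "alkylated"
  if (any(alk & is.na(meta$parent))) {
    stop("alkylated analytes must name a parent compound")
  }
  if (any(!alk & !is.na(meta$parent))) {
    stop("only alkylated analytes may carry a parent")
  }
  orphans <- setdiff(meta$parent[alk], meta$analyte)
  if (length(orphans) > 0L) {
    stop(sprintf("alkylated homolog(s) reference unknown parent(s): %s",
                 paste(orphans, collapse = ", ")))
  }
  for (col in c("rfd_mg_per_kg_day", "rpf", "lod_ng_per_g")) {
    v <- meta[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("'%s' must be strictly positive where present", col))
    }
  }
  invisible(meta)
}

#' Substitute left-censored nondetects at LOD/sqrt(2)
#'
#' The standard censoring convention for environmental chemistry data:
#' detected values pass through unchanged; every nondetect is assumed present
#' at its limit of detection divided by the square root of two.
#'
#' @param records Concentration table with columns `sample_id`, `analyte`,
#'   `value`, `nondetect`, `lod_ng_per_g` (as emitted by
#'   [generate_chemistry()] or read from CSV).
#' @return The table with `value` filled in everywhere (strictly positive) and
#'   the `nondetect` flag retained.
#' @export
#' @examples
#' substitute_nondetects(data.frame(sample_id = "S1", analyte = "pyrene",
#'   value = NA_real_, nondetect = TRUE, lod_ng_per_g = 10))  # value 7.0711
substitute_nondetects <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "analyte", "value", "nondetect", "lod_ng_per_g")
                %in% names(records)))
  nd <- records$nondetect
  bad <- nd & (is.na(records$lod_ng_per_g) | records$lod_ng_per_g <= 0)
  if (any(bad)) {
    off <- records[bad, c("sample_id", "analyte")]
    stop(sprintf("nondetect without a valid LOD: %s",
                 paste(sprintf("%s/%s", off$sample_id, off$analyte),
                       collapse = ", ")))
  }
  if (any(!nd & (is.na(records$value) | records$value <= 0))) {
    stop("detected records must carry a positive measured value")
  }
  out <- tibble::as_tibble(records)
  out$value[nd] <- out$lod_ng_per_g[nd] / sqrt(2)
  out
}

# pooled-RfD convention: anthracene and phenanthrene share a single oral
# reference dose, so their concentrations (and homologs) are summed into one
# pooled parent before hazard quotients are computed
default_rfd_pools <- function() {
  list("anthracene/phenanthrene" = c("anthracene", "phenanthrene"))
}

#' Per-sample parent totals for the noncancer assessment
#'
#' For every parent PAH with an accepted reference dose, sums the parent
#' concentration with all of its alkylated homologs (assumed equally toxic to
#' the parent); analytes with no RfD-bearing parent are excluded. Parents
#' sharing one RfD (anthracene/phenanthrene by default) are pooled into a
#' single row.
#'
#' @param concentrations Uncensored concentration table (run
#'   [substitute_nondetects()] first).
#' @param meta Analyte metadata.
#' @param pools Named list mapping a pooled label to the parent analytes it
#'   merges; default [default_rfd_pools()].
#' @return Tibble `sample_id`, `parent`, `rfd_mg_per_kg_day`,
#'   `total_ng_per_g`.
#' @export
parent_totals <- function(concentrations, meta, pools = default_rfd_pools()) {
  check_analyte_meta(meta)
  stopifnot(is.data.frame(concentrations))
  if (anyNA(concentrations$value)) {
    stop("parent_totals requires an uncensored table; run substitute_nondetects() first")
  }
  conc <- tibble::as_tibble(concentrations)
  idx <- match(conc$analyte, meta$analyte)
  if (anyNA(idx)) {
    stop(sprintf("concentration records for analytes missing from metadata: %s",
                 paste(unique(conc$analyte[is.na(idx)]), collapse = ", ")))
  }
  # each analyte contributes to itself (parents) or to its parent (homologs)
  target <- ifelse(meta$class[idx] == "alkylated", meta$parent[idx],
                   meta$analyte[idx])
  rfd_of <- stats::setNames(meta$rfd_mg_per_kg_day, meta$analyte)
  keep <- !is.na(rfd_of[target])
  conc <- conc[keep, , drop = FALSE]
  target <- target[keep]
  # apply pooling of parents that share an RfD
  pooled <- target
  for (label in names(pools)) {
    pooled[target %in% pools[[label]]] <- label
  }
  rfd_pooled <- rfd_of[target]
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sample_id = conc$sample_id, parent = pooled,
                     rfd_mg_per_kg_day = unname(rfd_pooled),
                     value = conc$value),
      .data$sample_id, .data$parent
    ),
    rfd_mg_per_kg_day = .data$rfd_mg_per_kg_day[1],
    total_ng_per_g = sum(.data$value),
    .groups = "drop"
  )
  out
}

#' Expand an analyte tier to its member analytes
#'
#' The tiers mirror the usual sensitivity analysis of widening the analyte
#' list used for carcinogenic potency: the seven priority carcinogenic PAHs
#' alone, plus the remaining unsubstituted PAHs, plus the alkylated homologs.
#' Tiers are strictly nested.
#'
#' @param tier One of `"cpah7"`, `"plus_unsubstituted"`, `"plus_alkylated"`.
#' @param meta Analyte metadata.
#' @return Character vector of analyte names.
#' @export
expand_analyte_tier <- function(tier = c("cpah7", "plus_unsubstituted",
                                         "plus_alkylated"), meta) {
  tier <- match.arg(tier)
  check_analyte_meta(meta)
  classes <- switch(tier,
    cpah7 = "cpah7",
    plus_unsubstituted = c("cpah7", "unsubstituted"),
    plus_alkylated = c("cpah7", "unsubstituted", "alkylated")
  )
  meta$analyte[meta$class %in% classes]
}

#' Benzo[a]pyrene-equivalent concentration per sample
#'
#' RPF-weighted sum of analyte concentrations over the analytes of a tier,
#' reported in ug BaP equivalents per kg shrimp (numerically identical to
#' ng/g wet weight). Analytes lacking an accepted RPF receive `default_rpf`
#' when one is supplied (the conservative tier-expansion convention assigns
#' 1, i.e. BaP's own potency); when `default_rpf` is `NULL` such analytes are
#' excluded, which is the 7-cPAH tier semantics.
#'
#' @param concentrations Uncensored concentration table (ng/g wet weight).
#' @param meta Analyte metadata.
#' @param tier Analyte tier, see [expand_analyte_tier()].
#' @param default_rpf Potency assigned to analytes without an accepted RPF,
#'   or `NULL` to exclude them.
#' @return Tibble `sample_id`, `bap_eq_ug_per_kg`.
#' @export
bap_equivalents <- function(concentrations, meta, tier = "cpah7",
                            default_rpf = NULL) {
  check_analyte_meta(meta)
  if (anyNA(concentrations$value)) {
    stop("bap_equivalents requires an uncensored table; run substitute_nondetects() first")
  }
  if (any(concentrations$value < 0)) {
    stop("validation error: negative concentration")
  }
  analytes <- expand_analyte_tier(tier, meta)
  conc <- concentrations[concentrations$analyte %in% analytes, , drop = FALSE]
  rpf <- meta$rpf[match(conc$analyte, meta$analyte)]
  if (is.null(default_rpf)) {
    keep <- !is.na(rpf)
    conc <- conc[keep, , drop = FALSE]
    rpf <- rpf[keep]
  } else {
    check_positive_scalar(default_rpf, "default_rpf")
    rpf[is.na(rpf)] <- default_rpf
  }
  dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sample_id = conc$sample_id,
                     weighted = rpf * conc$value),
      .data$sample_id
    ),
    bap_eq_ug_per_kg = sum(.data$weighted),
    .groups = "drop"
  )
}
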