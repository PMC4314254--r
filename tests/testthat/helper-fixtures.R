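# Small in-code fixtures shared across the suite.

# minimal analyte metadata: one cPAH, two RfD-bearing parents, one homolog,
# one analyte with neither parent nor RfD
tiny_meta <- function() {
  tibble::tibble(
    analyte = c("benzo[a]pyrene", "naphthalene", "2-methylnaphthalene",
                "pyrene", "perylene"),
    class = c("cpah7", "unsubstituted", "alkylated", "unsubstituted",
              "unsubstituted"),
    parent = c(NA, NA, "naphthalene", NA, NA),
    rfd_mg_per_kg_day = c(NA, 0.02, NA, 0.03, NA),
    rpf = c(1, NA, NA, NA, NA),
    lod_ng_per_g = c(1, 10, 2, 5, 5)
  )
}

conc_record <- function(sample_id, analyte, value = NA_real_,
                        nondetect = is.na(value), lod = 10) {
  tibble::tibble(sample_id = sample_id, analyte = analyte, value = value,
                 nondetect = nondetect, lod_ng_per_g = lod)
}

# fully censored concentration table over a metadata panel
censored_table <- function(meta, n_samples = 1L) {
  grid <- expand.grid(sample_id = sprintf("S%03d", seq_len(n_samples)),
                      analyte = meta$analyte, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = grid$sample_id,
    analyte = grid$analyte,
    value = NA_real_,
    nondetect = TRUE,
    lod_ng_per_g = meta$lod_ng_per_g[match(grid$analyte, meta$analyte)]
  )
}
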