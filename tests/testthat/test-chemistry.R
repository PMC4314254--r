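test_that("nondetect substitution maps LOD to LOD/sqrt(2) and passes detects", {
  rec <- rbind(
    conc_record("S1", "naphthalene", value = 1.5, lod = 10),
    conc_record("S1", "pyrene", lod = 10),
    conc_record("S2", "pyrene", lod = 1)
  )
  out <- substitute_nondetects(rec)
  expect_equal(out$value, c(1.5, 10 / sqrt(2), 1 / sqrt(2)))
  expect_equal(round(out$value[2], 4), 7.0711)
  expect_equal(round(out$value[3], 5), 0.70711)
  expect_true(all(out$value > 0))
  # substitution sits strictly below the LOD and detected values are unchanged
  expect_true(all(out$value[out$nondetect] < out$lod_ng_per_g[out$nondetect]))

  bad <- conc_record("S3", "pyrene", lod = NA_real_)
  expect_error(substitute_nondetects(bad), "S3/pyrene")
})

test_that("parent totals pool alkylated homologs into RfD-bearing parents", {
  meta <- tiny_meta()
  rec <- rbind(
    conc_record("S1", "naphthalene", value = 1.0),
    conc_record("S1", "2-methylnaphthalene", value = 0.5),
    conc_record("S1", "perylene", value = 0.4),
    conc_record("S2", "2-methylnaphthalene", value = 0.3),
    conc_record("S2", "naphthalene", lod = 1)  # censored parent
  )
  tot <- parent_totals(substitute_nondetects(rec), meta)
  s1 <- tot[tot$sample_id == "S1", ]
  expect_equal(s1$total_ng_per_g[s1$parent == "naphthalene"], 1.5)
  # no RfD and no RfD-bearing parent: excluded from noncancer totals
  expect_false("perylene" %in% tot$parent)
  s2 <- tot[tot$sample_id == "S2", ]
  expect_equal(s2$total_ng_per_g[s2$parent == "naphthalene"],
               1 / sqrt(2) + 0.3, tolerance = 1e-12)
})

test_that("anthracene and phenanthrene share one pooled RfD row", {
  meta <- load_analyte_meta()
  rec <- rbind(
    conc_record("S1", "anthracene", value = 0.4),
    conc_record("S1", "phenanthrene", value = 0.6),
    conc_record("S1", "1-methylphenanthrene", value = 0.2)
  )
  tot <- parent_totals(substitute_nondetects(rec), meta)
  expect_equal(tot$parent, "anthracene/phenanthrene")
  expect_equal(tot$total_ng_per_g, 1.2)
  expect_equal(tot$rfd_mg_per_kg_day, 0.3)
})

test_that("analyte tiers are strictly nested and cpah7 has the seven cPAHs", {
  meta <- load_analyte_meta()
  t1 <- expand_analyte_tier("cpah7", meta)
  t2 <- expand_analyte_tier("plus_unsubstituted", meta)
  t3 <- expand_analyte_tier("plus_alkylated", meta)
  expect_setequal(t1, c("benzo[a]anthracene", "chrysene",
                        "benzo[b]fluoranthene", "benzo[k]fluoranthene",
                        "benzo[a]pyrene", "indeno[1,2,3-c,d]pyrene",
                        "dibenzo[a,h]anthracene"))
  expect_true(all(t1 %in% t2) && length(t2) > length(t1))
  expect_true(all(t2 %in% t3) && length(t3) > length(t2))

  only7 <- meta[meta$class == "cpah7", ]
  expect_setequal(expand_analyte_tier("plus_alkylated", only7), t1)
})

test_that("BaP equivalents are RPF-weighted sums with tier monotonicity", {
  meta <- tiny_meta()
  rec <- substitute_nondetects(rbind(
    conc_record("S1", "benzo[a]pyrene", value = 1.0),
    conc_record("S1", "naphthalene", value = 2.0),
    conc_record("S1", "2-methylnaphthalene", value = 0.5)
  ))
  expect_equal(bap_equivalents(rec, meta, "cpah7")$bap_eq_ug_per_kg, 1.0)

  # weighted sum with an explicit default potency
  meta2 <- tiny_meta()
  meta2$rpf[meta2$analyte == "naphthalene"] <- 0.1
  two <- substitute_nondetects(rbind(
    conc_record("S1", "naphthalene", value = 2.0),
    conc_record("S1", "benzo[a]pyrene", value = 1.0)
  ))
  expect_equal(
    bap_equivalents(two, meta2, "plus_unsubstituted")$bap_eq_ug_per_kg,
    2.0 * 0.1 + 1.0)

  b1 <- bap_equivalents(rec, meta, "cpah7", default_rpf = NULL)$bap_eq_ug_per_kg
  b2 <- bap_equivalents(rec, meta, "plus_unsubstituted", default_rpf = 1)$bap_eq_ug_per_kg
  b3 <- bap_equivalents(rec, meta, "plus_alkylated", default_rpf = 1)$bap_eq_ug_per_kg
  expect_true(b1 <= b2 && b2 <= b3)
  expect_equal(b3, 1.0 + 2.0 + 0.5)
})

test_that("censored 7-cPAH panel reproduces the 0.668 ug/kg BaPeq constant", {
  meta <- load_analyte_meta()
  cens <- censored_table(meta[meta$class == "cpah7", ])
  bap <- bap_equivalents(substitute_nondetects(cens), meta, "cpah7")
  expect_equal(bap$bap_eq_ug_per_kg, 0.668, tolerance = 1e-3)
})
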