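# Abundant-taxon screen and treatment-specific set rules.

test_that("the 25-feature toy table yields exactly the 5 planted risers", {
  toy <- toy_riser_table()
  got <- abundant_asvs(toy$abund, toy$metadata, "CIF")
  expect_setequal(got, sprintf("riser_%d", 1:5))
})

test_that("a feature outside the top rank in one flask is excluded", {
  toy <- toy_riser_table(stuck_replicate = "III")
  got <- abundant_asvs(toy$abund, toy$metadata, "CIF")
  expect_setequal(got, sprintf("riser_%d", c(1, 2, 3, 5)))
  detail <- attr(got, "detail")
  expect_false(detail$rank_ok[detail$feature_id == "riser_4"])
})

test_that("a top-ranked but constant feature fails the fold rule", {
  toy <- toy_riser_table()
  detail <- attr(abundant_asvs(toy$abund, toy$metadata, "CIF"), "detail")
  expect_true(detail$rank_ok[detail$feature_id == "bg_01"])   # always rank 1-ish
  expect_false(detail$fold_ok[detail$feature_id == "bg_01"])
})

test_that("a zero day-0 abundance passes the fold rule once positive later", {
  toy <- toy_riser_table()
  abund <- toy$abund
  abund["riser_1", toy$metadata$day == 0] <- 0
  got <- abundant_asvs(abund, toy$metadata, "CIF")
  expect_true("riser_1" %in% got)
  expect_error(abundant_asvs(abund[, toy$metadata$day != 0],
                             toy$metadata, "CIF"), "day 0")
})

test_that("treatment-specific ASVs need exclusivity plus enrichment", {
  abundant <- list(control = c("shared_all"),
                   CIF = c("shared_all", "cif_only", "cif_weak", "cif_hif"),
                   HIF = c("shared_all", "hif_only", "cif_hif"))
  lef <- data.frame(
    feature_id = c("shared_all", "cif_only", "cif_weak", "cif_hif", "hif_only"),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    enriched_class = c("CIF", "CIF", NA, "CIF", "HIF"),
    stringsAsFactors = FALSE)
  spec <- treatment_specific_asvs(abundant, lef)
  expect_setequal(spec$feature_id[spec$treatment == "CIF"], "cif_only")
  expect_setequal(spec$feature_id[spec$treatment == "HIF"], "hif_only")
  # abundant in both treatments -> in neither specific set
  expect_false("cif_hif" %in% spec$feature_id)
  # disjointness invariant
  expect_length(intersect(spec$feature_id[spec$treatment == "CIF"],
                          spec$feature_id[spec$treatment == "HIF"]), 0)
})

test_that("the burst threshold discards sub-burst vOTUs regardless of p", {
  samples <- sprintf("CIF_%s_d%d", rep(c("I", "II", "III"), 3),
                     rep(c(0, 3, 5), each = 3))
  md <- sample_metadata(data.frame(
    sample_id = samples, treatment = "CIF",
    replicate = rep(c("I", "II", "III"), 3),
    day = rep(c(0L, 3L, 5L), each = 3)))
  pmat <- matrix(c(rep(9, 3), rep(90, 6),        # perfect 10x rise, peak 90
                   rep(1e4, 9),                  # flat and high
                   rep(100, 3), rep(1e5, 6)),    # genuine burst
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("v_low", "v_flat", "v_burst"), samples))
  lef <- data.frame(feature_id = rownames(pmat),
                    significant = c(TRUE, FALSE, TRUE),
                    enriched_class = c("after", NA, "after"),
                    stringsAsFactors = FALSE)
  got <- increased_votus(pmat, md, lef, burst_threshold = 100)
  expect_identical(as.character(got), "v_burst")
})

test_that("specific vOTU sets partition by treatment membership", {
  increased <- list(control = c("v_all", "v_ctrl"),
                    CIF = c("v_all", "v_both", "v_cif"),
                    HIF = c("v_all", "v_both", "v_hif"))
  res <- treatment_specific_votus(increased)
  expect_setequal(res$specific$feature_id[res$specific$treatment == "CIF"], "v_cif")
  expect_setequal(res$specific$feature_id[res$specific$treatment == "HIF"], "v_hif")
  expect_identical(res$both, "v_both")
  expect_identical(res$all, "v_all")
  expect_false("v_ctrl" %in% res$specific$feature_id)
})

test_that("raising the planted enrichment never loses a recovered feature", {
  base_cfg <- small_sim_config()
  sim_lo <- simulate_microcosm(base_cfg, seed = 17)
  sim_hi <- simulate_microcosm(small_sim_config(responder_enrichment = 20),
                               seed = 17)
  res_lo <- find_specific_asvs(sim_lo$dataset, bloom_config(seed = 17))
  res_hi <- find_specific_asvs(sim_hi$dataset, bloom_config(seed = 17))
  planted <- sim_lo$truth$asv$feature_id
  rec_lo <- intersect(res_lo$specific$feature_id, planted)
  rec_hi <- intersect(res_hi$specific$feature_id, planted)
  expect_true(all(rec_lo %in% rec_hi))
})
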