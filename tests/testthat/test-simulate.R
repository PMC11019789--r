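# Synthetic generators: determinism, invariants, ground-truth dynamics.

test_that("identical seeds give byte-identical bundles", {
  s1 <- simulate_microcosm(small_sim_config(), seed = 9)
  s2 <- simulate_microcosm(small_sim_config(), seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_microcosm(small_sim_config(), seed = 10)
  expect_false(identical(unclass(s1$dataset$counts),
                         unclass(s3$dataset$counts)))
  e1 <- simulate_environment(small_sim_config(), seed = 9)
  e2 <- simulate_environment(small_sim_config(), seed = 9)
  expect_identical(e1, e2)
})

test_that("generated bundles pass validation and their file round trip", {
  sim <- simulate_microcosm(small_sim_config(), seed = 2)
  expect_s3_class(sim$dataset, "bloom_dataset")
  expect_match(attr(sim$dataset, "validation"), "0 errors")
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir, seed = 2)
  ds2 <- load_dataset(file.path(dir, "feature_table.tsv"),
                      file.path(dir, "metadata.tsv"),
                      file.path(dir, "taxonomy.tsv"),
                      file.path(dir, "cytometry.tsv"),
                      file.path(dir, "votu_quant.tsv"),
                      file.path(dir, "host_predictions.tsv"),
                      config = bloom_config(min_reads_amplicon = 1,
                                            min_reads_virome = 1))
  expect_equal(unclass(ds2$counts), unclass(sim$dataset$counts))
  expect_equal(ds2$votu$fpkm, sim$dataset$votu$fpkm, tolerance = 1e-12)
})

test_that("read-count columns sum exactly to the configured depth", {
  cfg <- small_sim_config(depth_amplicon = 3123L)
  sim <- simulate_microcosm(cfg, seed = 4)
  expect_true(all(colSums(sim$dataset$counts) == 3123L))
})

test_that("the vOTU quantification invariant holds in every sample", {
  for (s in 1:3) {
    vq <- simulate_microcosm(small_sim_config(), seed = 30 + s)$dataset$votu
    expect_true(all(colSums(vq$fpkm) <= vq$sample_info$fpkm_viral_total * (1 + 1e-9)))
  }
})

test_that("planted responders more than double their latent density by day 4", {
  sim <- simulate_microcosm(sim_config(), seed = 1)
  truth <- sim$truth
  cif <- truth$asv$feature_id[truth$asv$responder_class == "CIF"]
  md <- sim$dataset$metadata
  for (f in cif) {
    for (r in c("I", "II", "III")) {
      d0 <- truth$latent_cells[f, sprintf("CIF_%s_d0", r)]
      d4 <- truth$latent_cells[f, sprintf("CIF_%s_d4", r)]
      expect_gt(d4, 2 * d0)
    }
  }
  # total cell density has the right order of magnitude (~1e6/mL)
  expect_true(all(sim$dataset$cytometry$cells_per_ml > 1e5 &
                    sim$dataset$cytometry$cells_per_ml < 1e7))
})

test_that("with no planted effects, treatments are exchangeable", {
  cfg <- small_sim_config(
    n_background_asvs = 40L,
    n_responders = c(CIF = 0L, HIF = 0L, both = 0L, all = 0L))
  sim <- simulate_microcosm(cfg, seed = 6)
  lat <- sim$truth$latent_cells
  md <- sim$dataset$metadata
  pass <- vapply(rownames(lat), function(f) {
    ks <- suppressWarnings(
      ks.test(lat[f, md$sample_id[md$treatment == "CIF"]],
              lat[f, md$sample_id[md$treatment == "control"]]))
    ks$p.value >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("environmental pairs hit their configured association strength", {
  rs <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_environment(sim_config(n_env_pairs = 2, n_env_null = 0),
                                seed = 300 + s)
    for (i in 1:2) {
      rs <- c(rs, cor(rank(sim$env$asv[sim$truth$asv_id[i], ]),
                      rank(sim$env$votu[sim$truth$votu_id[i], ])))
    }
  }
  expect_lt(abs(mean(rs) - 0.9), 0.15)
  expect_error(simulate_environment(sim_config(n_timepoints = 4L), 1),
               "n_timepoints")
})

test_that("generator rejects degenerate configurations", {
  expect_error(sim_config(depth_amplicon = 0), "depth_amplicon")
  expect_error(sim_config(n_background_asvs = 0), "n_background_asvs")
})
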