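# Taxonomy-guided candidate pairing and co-occurrence confirmation.

make_tax <- function() taxonomy_table(data.frame(
  feature_id = c("asv_polar", "asv_rhodo"),
  domain = "Bacteria",
  phylum = c("Bacteroidetes", "Proteobacteria"),
  class = c("Bacteroidia", "Alphaproteobacteria"),
  order = c("Flavobacteriales", "Rhodobacterales"),
  family = c("Flavobacteriaceae", "Rhodobacteraceae"),
  genus = c("Polaribacter", "Planktomarina"),
  confidence = 1))

make_host <- function() host_prediction(data.frame(
  votu_id = c("v_bacter", "v_gamma", "v_unknown"),
  host_rank = c("phylum", "class", ""),
  host_taxon = c("Bacteroidetes", "Gammaproteobacteria", ""),
  gotu = c("g509", "g100", "g001"),
  lysogenic = FALSE))

test_that("host taxonomy matching pairs along the lineage path", {
  pairs <- candidate_pairs(c("asv_polar", "asv_rhodo"),
                           c("v_bacter", "v_gamma", "v_unknown"),
                           make_tax(), make_host(), treatment = "CIF")
  # phylum-level host prediction matches the Bacteroidetes ASV only
  bac <- pairs[pairs$votu_id == "v_bacter", ]
  expect_identical(bac$asv_id, "asv_polar")
  expect_identical(bac$match_basis, "host-taxonomy:phylum")
  # class-level Gammaproteobacteria matches neither lineage
  expect_false("v_gamma" %in% pairs$votu_id)
  # host-unknown vOTUs are screened against every specific ASV
  unk <- pairs[pairs$votu_id == "v_unknown", ]
  expect_setequal(unk$asv_id, c("asv_polar", "asv_rhodo"))
  expect_true(all(unk$match_basis == "host-unknown screen"))
})

test_that("pair significance is exactly the three-threshold conjunction", {
  sim <- simulate_environment(sim_config(n_env_pairs = 4, n_env_null = 8,
                                         env_strength = 0.6), seed = 21)
  null_ids <- sprintf("%02d", 1:8)
  cand <- data.frame(
    treatment = "CIF",
    asv_id = c(sim$truth$asv_id, paste0("envASV_null_", null_ids)),
    votu_id = c(sim$truth$votu_id, paste0("envvOTU_null_", null_ids)),
    match_basis = "host-unknown screen", stringsAsFactors = FALSE)
  res <- significant_pairs(cand, sim$env, bloom_config(seed = 21))
  manual <- !res$degenerate & res$r > 0.6 & res$p < 0.01 & res$q < 0.05
  expect_identical(res$significant, manual)
  # an r below the threshold fails no matter how small its p-value
  expect_false(any(res$significant[res$r <= 0.6]))
})

test_that("confirmation on the environmental series respects thresholds", {
  sim <- simulate_environment(sim_config(n_env_pairs = 2, n_env_null = 3,
                                         env_strength = 1), seed = 3)
  truth <- sim$truth
  cand <- data.frame(treatment = "CIF",
                     asv_id = c(truth$asv_id, "envASV_null_01"),
                     votu_id = c(truth$votu_id, "envvOTU_null_01"),
                     match_basis = "host-taxonomy:genus",
                     stringsAsFactors = FALSE)
  res <- significant_pairs(cand, sim$env, bloom_config(seed = 3))
  expect_equal(res$r[1:2], c(1, 1))
  expect_true(all(res$significant[1:2]))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(
    significant_pairs(cand,
                      env_series(sim$env$asv[, 1:4], sim$env$votu[, 1:4]),
                      bloom_config()),
    "5 shared time points")
  cand_bad <- cand; cand_bad$asv_id[1] <- "missing_asv"
  expect_error(significant_pairs(cand_bad, sim$env, bloom_config()),
               "missing_asv")
})

test_that("perfect association gives r = 1 and zero strength matches the null", {
  sim1 <- simulate_environment(sim_config(n_env_pairs = 3, env_strength = 1),
                               seed = 11)
  for (i in 1:3) {
    sp <- spearman_perm(sim1$env$asv[sim1$truth$asv_id[i], ],
                        sim1$env$votu[sim1$truth$votu_id[i], ],
                        n_permutations = 99, seed = 1)
    expect_equal(sp$r, 1)
  }
  rs <- vapply(1:20, function(s) {
    sim0 <- simulate_environment(sim_config(n_env_pairs = 1, n_env_null = 0,
                                            env_strength = 0), seed = s)
    cor(rank(sim0$env$asv[1, ]), rank(sim0$env$votu[1, ]))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)  # centred on zero under the null
})

test_that("microcosm candidates chain through to environmental confirmation", {
  sim <- simulate_microcosm(small_sim_config(votus_per_responder = 2L),
                            seed = 31)
  res <- run_microcosm(sim$dataset, bloom_config(seed = 31), community = FALSE)
  env_sim <- simulate_environment(
    small_sim_config(), seed = 31,
    asv_ids = rownames(sim$dataset$counts),
    votu_ids = rownames(sim$dataset$votu$fpkm),
    pairs = data.frame(asv_id = sim$truth$votu$host_asv,
                       votu_id = sim$truth$votu$votu_id,
                       stringsAsFactors = FALSE))
  expect_gt(nrow(res$candidate_pairs), 0)
  pairs <- confirm_pairs(res, env_sim$env)
  expect_true(all(c("r", "p", "q", "significant") %in% names(pairs)))
  # taxonomy-matched true pairs carry a strong planted correlation
  truly <- paste(pairs$asv_id, pairs$votu_id) %in%
    paste(sim$truth$votu$host_asv, sim$truth$votu$votu_id)
  tax_matched <- truly & startsWith(pairs$match_basis, "host-taxonomy")
  expect_gt(sum(tax_matched), 0)
  expect_gte(mean(pairs$significant[tax_matched]), 0.5)
})
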