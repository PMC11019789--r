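# Fixtures are built in code: small generator configurations for cheap
# randomized bundles, and a hand-built deterministic abundance table for
# the filtering rules.

small_sim_config <- function(...) {
  defaults <- list(n_background_asvs = 12L,
                   n_responders = c(CIF = 1L, HIF = 1L, both = 0L, all = 0L),
                   n_background_votus = 8L,
                   votus_per_responder = 1L,
                   lysogenic_per_treatment = 0L,
                   depth_amplicon = 2000L,
                   depth_virome = 1e5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Tiny 3-sample bundle assembled by hand (no randomness) for IO tests.
toy_dataset <- function() {
  counts <- matrix(c(10L, 30L, 0L,
                     5L, 5L, 90L,
                     1L, 0L, 9L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("ASV_a", "ASV_b", "ASV_c"),
                                   c("control_I_d0", "control_I_d1", "CIF_I_d0")))
  md <- data.frame(sample_id = colnames(counts),
                   treatment = c("control", "control", "CIF"),
                   replicate = c("I", "I", "I"),
                   day = c(0L, 1L, 0L))
  cyt <- data.frame(treatment = c("control", "control", "CIF"),
                    replicate = "I", day = c(0L, 1L, 0L),
                    cells_per_ml = c(1e6, 1.2e6, 9e5),
                    particles_per_ml = c(2e6, 2.1e6, 1.9e6))
  tax <- data.frame(feature_id = rownames(counts),
                    domain = "Bacteria",
                    phylum = c("Bacteroidetes", "Proteobacteria", "Proteobacteria"),
                    class = c("Bacteroidia", "Gammaproteobacteria", "Alphaproteobacteria"),
                    order = c("Flavobacteriales", "Vibrionales", "Rhodobacterales"),
                    family = c("Flavobacteriaceae", "Vibrionaceae", ""),
                    genus = c("Polaribacter", "Vibrio", ""),
                    confidence = c(0.99, 0.9, 0.7))
  fpkm <- matrix(c(10, 20, 0,
                   5, 0, 40), nrow = 2, byrow = TRUE,
                 dimnames = list(c("vOTU_x", "vOTU_y"), colnames(counts)))
  si <- data.frame(sample_id = colnames(counts),
                   fpkm_viral_total = c(100, 50, 80),
                   r_viral = c(9000L, 8000L, 7000L),
                   r_potential = c(1000L, 2000L, 3000L))
  vq <- votu_quant(fpkm, c(vOTU_x = 15000L, vOTU_y = 22000L), si)
  host <- data.frame(votu_id = c("vOTU_x", "vOTU_y"),
                     host_rank = c("phylum", ""),
                     host_taxon = c("Bacteroidetes", ""),
                     gotu = c("g405", "g001"),
                     lysogenic = c(FALSE, TRUE))
  bloom_dataset(counts, md, tax, cyt, vq, host)
}

# Deterministic 25-feature toy abundance table for one treatment:
# 20 constant background features and 5 planted risers that start below
# the top 20 and rise past it with a clear fold change.
toy_riser_table <- function(stuck_replicate = NULL) {
  days <- 0:3
  reps <- c("I", "II", "III")
  ids <- c(sprintf("bg_%02d", 1:20), sprintf("riser_%d", 1:5))
  samples <- as.vector(outer(reps, days, function(r, d) sprintf("CIF_%s_d%d", r, d)))
  md <- data.frame(sample_id = samples,
                   treatment = "CIF",
                   replicate = rep(reps, times = length(days)),
                   day = rep(days, each = length(reps)))
  abund <- matrix(0, nrow = 25, ncol = length(samples),
                  dimnames = list(ids, samples))
  for (s in seq_along(samples)) {
    d <- md$day[s]
    abund[1:20, s] <- (21 - (1:20)) * 1000          # constants 20000..1000
    abund[21:25, s] <- if (d >= 2) 30000 else 100   # risers
    if (!is.null(stuck_replicate) && md$replicate[s] == stuck_replicate) {
      abund["riser_4", s] <- 100                    # never reaches the top
    }
  }
  list(abund = abund, metadata = sample_metadata(md))
}

# Recovery bookkeeping shared by end-to-end tests: compares called
# treatment-specific features with planted truth.
recovery_counts <- function(called, truth_by_class) {
  tp <- sum(called$feature_id[called$treatment == "CIF"] %in% truth_by_class$CIF) +
    sum(called$feature_id[called$treatment == "HIF"] %in% truth_by_class$HIF)
  n_truth <- length(truth_by_class$CIF) + length(truth_by_class$HIF)
  c(tp = tp, called = nrow(called), truth = n_truth)
}
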