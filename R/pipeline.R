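# High-level orchestration: chains calibration, screening, enrichment and
# pairing over a dataset bundle.

#' Detect treatment-specific ASVs
#'
#' Calibrates ASV counts to approximate cell numbers, screens each
#' treatment for abundant ASVs (top-rank + fold rules), runs the
#' class/subclass enrichment test over the union of abundant ASVs with
#' treatment as class and replicate flask as subclass, and intersects the
#' two.
#'
#' @param ds A [bloom_dataset()].
#' @param config A [bloom_config()].
#' @return List with `cells` (calibrated table), `abundant` (per-treatment
#'   id vectors), `lefse` (enrichment results) and `specific` (data frame).
#' @export
find_specific_asvs <- function(ds, config = bloom_config()) {
  cells <- asv_cell_table(ds)
  md <- ds$metadata[colnames(cells), , drop = FALSE]
  treatments <- intersect(TREATMENTS, unique(md$treatment))
  abundant <- lapply(stats::setNames(treatments, treatments), function(tr) {
    abundant_asvs(cells, ds$metadata, tr, top_rank = config$top_rank,
                  fold = config$fold, fold_on_means = config$fold_on_means)
  })
  union_ids <- unique(unlist(abundant))
  if (length(union_ids) == 0L) {
    return(list(cells = cells, abundant = abundant, lefse = NULL,
                specific = treatment_specific_asvs(abundant,
                  data.frame(feature_id = character(0),
                             significant = logical(0),
                             enriched_class = character(0)))))
  }
  lef <- lefse(cells[union_ids, , drop = FALSE],
               classes = md$treatment, subclasses = md$replicate,
               alpha = config$lefse_alpha, lda_threshold = config$lda_threshold,
               n_boot = config$lda_boot, frac = config$lda_frac,
               seed = config$seed)
  list(cells = cells, abundant = abundant, lefse = lef,
       specific = treatment_specific_asvs(abundant, lef))
}

#' Detect increased and treatment-specific vOTUs
#'
#' Calibrates vOTU FPKM to approximate particle numbers, and within each
#' treatment tests every vOTU for a significant increase after day 0
#' (day 0 versus later as class, replicate flask as subclass), keeping
#' vOTUs whose replicate-mean particle number exceeds the burst threshold
#' on at least one day. Treatment-specific vOTUs increased in exactly one
#' of CIF/HIF.
#'
#' @param ds A [bloom_dataset()] with virome quantification.
#' @param config A [bloom_config()].
#' @return List with `particles` (calibrated table), `increased`
#'   (per-treatment id vectors), `lefse` (per-treatment results) and
#'   `specific` (list from [treatment_specific_votus()]).
#' @export
find_specific_votus <- function(ds, config = bloom_config()) {
  particles <- votu_particle_table(ds)
  md <- ds$metadata[colnames(particles), , drop = FALSE]
  treatments <- intersect(TREATMENTS, unique(md$treatment))
  lef <- list(); increased <- list()
  for (tr in treatments) {
    cols <- md$sample_id[md$treatment == tr]
    sub <- particles[, cols, drop = FALSE]
    day <- md$day[match(cols, md$sample_id)]
    keep <- day == 0L | day >= config$after_day_min
    sub <- sub[, keep, drop = FALSE]
    day <- day[keep]
    cls <- ifelse(day == 0L, "day0", "after")
    repl <- md$replicate[match(colnames(sub), md$sample_id)]
    lef[[tr]] <- lefse(sub, classes = cls, subclasses = repl,
                       alpha = config$lefse_alpha,
                       lda_threshold = config$lda_threshold,
                       n_boot = config$lda_boot, frac = config$lda_frac,
                       seed = config$seed)
    increased[[tr]] <- increased_votus(sub, ds$metadata, lef[[tr]],
                                       burst_threshold = config$burst_threshold)
  }
  list(particles = particles, increased = increased, lefse = lef,
       specific = treatment_specific_votus(increased))
}

#' Run the full microcosm inference pipeline
#'
#' Community structure (rarefaction, Bray-Curtis, PCoA, ANOSIM contrasts),
#' phase-wise cytometry comparisons, treatment-specific ASV and vOTU
#' detection, and taxonomy-guided candidate host-virus pairs.
#'
#' @param ds A [bloom_dataset()].
#' @param config A [bloom_config()].
#' @param community Run the community-structure stage (default `TRUE`;
#'   skipping it avoids rarefaction when only responder detection is
#'   needed).
#' @return List with elements `community`, `phase_tests`, `asvs`, `votus`,
#'   `candidate_pairs`, `config`.
#' @export
run_microcosm <- function(ds, config = bloom_config(), community = TRUE) {
  comm <- if (community) community_structure(ds, config)
  phase_tests <- rbind(
    cbind(metric = "cells", phase_compare(ds$cytometry, "cells")),
    cbind(metric = "particles", phase_compare(ds$cytometry, "particles")))
  asvs <- find_specific_asvs(ds, config)
  votus <- if (!is.null(ds$votu)) find_specific_votus(ds, config)
  cand <- NULL
  if (!is.null(votus) && !is.null(ds$host) && !is.null(ds$taxonomy)) {
    cand <- do.call(rbind, lapply(c("CIF", "HIF"), function(tr) {
      candidate_pairs(
        asvs$specific$feature_id[asvs$specific$treatment == tr],
        votus$specific$specific$feature_id[votus$specific$specific$treatment == tr],
        ds$taxonomy, ds$host, treatment = tr)
    }))
  }
  list(community = comm, phase_tests = phase_tests, asvs = asvs,
       votus = votus, candidate_pairs = cand, config = config)
}

#' Confirm microcosm-derived candidate pairs on an environmental series
#'
#' @param result Output of [run_microcosm()].
#' @param env An [env_series()].
#' @param config A [bloom_config()].
#' @return [significant_pairs()] output over all candidates.
#' @export
confirm_pairs <- function(result, env, config = result$config) {
  if (is.null(result$candidate_pairs) || nrow(result$candidate_pairs) == 0L) {
    bt_stop("no candidate pairs to confirm")
  }
  significant_pairs(result$candidate_pairs, env, config)
}

#' Write pipeline results as TSV files
#'
#' @param result Output of [run_microcosm()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- result$config$seed
  if (!is.null(result$community)) {
    ord <- result$community$ordination
    write_bt_tsv(data.frame(sample_id = rownames(ord$coordinates),
                            ord$coordinates, check.names = FALSE),
                 file.path(dir, "pcoa_coordinates.tsv"), seed)
    write_bt_tsv(result$community$anosim, file.path(dir, "anosim.tsv"), seed)
    d <- result$community$distance
    write_bt_tsv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
                 file.path(dir, "bray_curtis.tsv"), seed)
  }
  write_bt_tsv(result$phase_tests, file.path(dir, "phase_tests.tsv"), seed)
  if (!is.null(result$asvs$lefse)) {
    write_bt_tsv(result$asvs$lefse, file.path(dir, "differential_asvs.tsv"), seed)
  }
  write_bt_tsv(result$asvs$specific, file.path(dir, "specific_asvs.tsv"), seed)
  if (!is.null(result$votus)) {
    write_bt_tsv(result$votus$specific$specific,
                 file.path(dir, "specific_votus.tsv"), seed)
  }
  if (!is.null(result$candidate_pairs)) {
    write_bt_tsv(result$candidate_pairs, file.path(dir, "candidate_pairs.tsv"), seed)
  }
  invisible(dir)
}
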