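#' Pipeline configuration
#'
#' Collects every tunable threshold of the inference pipeline in one place.
#' Defaults follow the study design the pipeline reproduces: amplicon reads
#' rarefied to 9,450 reads per sample, samples under 5,000 amplicon reads
#' (10,000 virome reads) dropped, abundant taxa screened by top-20 rank and
#' 2-fold increase over day 0, viral increases gated by a 100 particles/mL
#' burst-size threshold, the class/subclass enrichment test run at alpha 0.05
#' with a linear-discriminant log10 effect-size threshold of 2.0, and
#' co-occurrence links called at Spearman r > 0.6, permutation P < 0.01 and
#' Benjamini-Hochberg q < 0.05.
#'
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param min_reads_amplicon Minimum amplicon reads for a sample to be kept.
#' @param min_reads_virome Minimum virome reads for a sample to be kept.
#' @param top_rank Rank cutoff for the abundant-taxon screen.
#' @param fold Fold-increase over day 0 required by the abundant-taxon screen.
#' @param burst_threshold Minimum peak particle density (particles/mL) a vOTU
#'   must reach to be called increased; motivated by typical burst sizes of
#'   marine bacterial viruses (50-185 particles per lysed cell, ~100 on
#'   average).
#' @param lefse_alpha Kruskal-Wallis alpha of the enrichment test.
#' @param lda_threshold Minimum log10 linear-discriminant effect size.
#' @param lda_boot Bootstrap rounds of the effect-size stage.
#' @param lda_frac Subsampling fraction per bootstrap round.
#' @param r_threshold Minimum Spearman r for a significant co-occurrence.
#' @param p_threshold Maximum permutation p for a significant co-occurrence.
#' @param q_threshold Maximum Benjamini-Hochberg q for a significant
#'   co-occurrence.
#' @param n_permutations Permutations for Monte-Carlo p-values (Spearman,
#'   ANOSIM).
#' @param after_day_min First day of the "after" class in the day-0-versus-
#'   later viral increase test. The default 2 reads "after day 1" literally:
#'   the after class holds the virome days beyond day 1 (days 3, 5, 7 in
#'   the reference design) and day-1 samples enter neither class. Set to 1
#'   to pool day 1 into the after class instead.
#' @param fold_on_means If `TRUE` (default) the fold criterion of the
#'   abundant-taxon screen is evaluated on replicate means; if `FALSE`,
#'   per flask.
#' @param seed Integer seed recorded in every derived output.
#'
#' @return An object of class `bloom_config` (a named list).
#' @export
#' @examples
#' cfg <- bloom_config(seed = 42)
#' cfg$rarefaction_depth
bloom_config <- function(rarefaction_depth = 9450,
                         min_reads_amplicon = 5000,
                         min_reads_virome = 10000,
                         top_rank = 20,
                         fold = 2.0,
                         burst_threshold = 100,
                         lefse_alpha = 0.05,
                         lda_threshold = 2.0,
                         lda_boot = 30,
                         lda_frac = 2 / 3,
                         r_threshold = 0.6,
                         p_threshold = 0.01,
                         q_threshold = 0.05,
                         n_permutations = 999,
                         after_day_min = 2,
                         fold_on_means = TRUE,
                         seed = 1L) {
  cfg <- list(
    rarefaction_depth = rarefaction_depth,
    min_reads_amplicon = min_reads_amplicon,
    min_reads_virome = min_reads_virome,
    top_rank = top_rank,
    fold = fold,
    burst_threshold = burst_threshold,
    lefse_alpha = lefse_alpha,
    lda_threshold = lda_threshold,
    lda_boot = lda_boot,
    lda_frac = lda_frac,
    r_threshold = r_threshold,
    p_threshold = p_threshold,
    q_threshold = q_threshold,
    n_permutations = n_permutations,
    after_day_min = after_day_min,
    fold_on_means = isTRUE(fold_on_means),
    seed = as.integer(seed)
  )
  numeric_fields <- setdiff(names(cfg), c("fold_on_means", "seed", "after_day_min"))
  for (f in numeric_fields) {
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0) {
      bt_stop("config field '", f, "' must be a positive scalar")
    }
  }
  if (!is_scalar_num(cfg$after_day_min) || cfg$after_day_min < 1) {
    bt_stop("config field 'after_day_min' must be >= 1")
  }
  structure(cfg, class = "bloom_config")
}

#' @export
print.bloom_config <- function(x, ...) {
  cat("bloomtrack pipeline configuration\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
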