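# Taxonomy-guided host-virus candidate pairing and its confirmation by
# thresholded Spearman co-occurrence on the environmental time series.

#' Candidate host-virus pairs within one treatment
#'
#' A (ASV, vOTU) pair is emitted when the vOTU's predicted host taxon
#' equals the ASV's lineage entry at the predicted rank or at any coarser
#' rank on the lineage path (a phylum-level host prediction matches any ASV
#' of that phylum). vOTUs without a host prediction are screened against
#' every specific ASV of the same treatment (`match_basis =
#' "host-unknown screen"`).
#'
#' @param specific_asvs Character vector of treatment-specific ASV ids.
#' @param specific_votus Character vector of treatment-specific vOTU ids.
#' @param taxonomy [taxonomy_table()] covering the ASVs.
#' @param host [host_prediction()] covering the vOTUs.
#' @param treatment Treatment label carried into the output.
#' @return Data frame: treatment, asv_id, votu_id, match_basis.
#' @export
candidate_pairs <- function(specific_asvs, specific_votus, taxonomy, host,
                            treatment = NA_character_) {
  rows <- list()
  for (v in specific_votus) {
    hp <- host[host$votu_id == v, , drop = FALSE]
    unknown <- nrow(hp) == 0L || !nzchar(hp$host_taxon[1L])
    if (unknown) {
      for (a in specific_asvs) {
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = treatment, asv_id = a, votu_id = v,
          match_basis = "host-unknown screen", stringsAsFactors = FALSE)
      }
    } else {
      rank_idx <- match(hp$host_rank[1L], TAXONOMY_RANKS)
      for (a in specific_asvs) {
        lineage <- as.character(taxonomy[a, TAXONOMY_RANKS[seq_len(rank_idx)]])
        hit <- which(lineage == hp$host_taxon[1L])
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            treatment = treatment, asv_id = a, votu_id = v,
            match_basis = paste0("host-taxonomy:", TAXONOMY_RANKS[max(hit)]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), asv_id = character(0),
               votu_id = character(0), match_basis = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Confirm candidate pairs by co-occurrence on the environmental series
#'
#' For each candidate pair, computes the Spearman correlation (no time lag)
#' between the ASV relative abundance and the vOTU FPKM over the shared
#' time points, with a two-sided permutation p-value; q-values are
#' Benjamini-Hochberg over all tested pairs jointly. A pair is significant
#' exactly when `r > r_threshold`, `p < p_threshold` and
#' `q < q_threshold`; constant (degenerate) series can never be
#' significant.
#'
#' @param pairs Candidate-pair data frame from [candidate_pairs()].
#' @param env An [env_series()].
#' @param config A [bloom_config()] (thresholds, permutations, seed).
#' @return The pair data frame with added columns `r`, `p`, `q`,
#'   `degenerate`, `significant`.
#' @export
significant_pairs <- function(pairs, env, config = bloom_config()) {
  if (nrow(pairs) == 0L) {
    pairs$r <- pairs$p <- pairs$q <- numeric(0)
    pairs$degenerate <- pairs$significant <- logical(0)
    return(pairs)
  }
  n_tp <- ncol(env$asv)
  if (n_tp < 5L) bt_stop("need >= 5 shared time points; got ", n_tp)
  miss_a <- setdiff(unique(pairs$asv_id), rownames(env$asv))
  miss_v <- setdiff(unique(pairs$votu_id), rownames(env$votu))
  if (length(miss_a) || length(miss_v)) {
    bt_stop("feature(s) absent from environmental series: ",
            paste(c(miss_a, miss_v), collapse = ", "))
  }
  r <- p <- numeric(nrow(pairs))
  degenerate <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sp <- spearman_perm(env$asv[pairs$asv_id[i], ],
                        env$votu[pairs$votu_id[i], ],
                        n_permutations = config$n_permutations,
                        seed = config$seed + i)
    r[i] <- sp$r; p[i] <- sp$p; degenerate[i] <- sp$degenerate
  }
  q <- bh_fdr(p)
  pairs$r <- r
  pairs$p <- p
  pairs$q <- q
  pairs$degenerate <- degenerate
  pairs$significant <- !degenerate & r > config$r_threshold &
    p < config$p_threshold & q < config$q_threshold
  attr(pairs, "seed") <- config$seed
  pairs
}
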