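# Filtering rules that call abundant ASVs, treatment-specific ASVs,
# increased vOTUs and treatment-specific vOTUs from calibrated abundance
# tables plus enrichment results.

#' Abundant features of one treatment
#'
#' A feature is abundant if (i) on at least one day after day 0 it ranks in
#' the top `top_rank` of the approximate abundance in every replicate flask
#' sampled that day, and (ii) its abundance exceeds `fold` times its day-0
#' abundance at least once. Ties at the rank cutoff are included
#' (competition ranking). Criterion (ii) is evaluated on replicate means by
#' default (`fold_on_means`), or per flask; a day-0 abundance of exactly 0
#' passes whenever any later value is positive. Missing flask-days are
#' tolerated: the rank condition is evaluated over the flasks actually
#' sampled, and the reduced n is logged.
#'
#' @param abund Absolute-abundance matrix (features x samples).
#' @param metadata [sample_metadata()] covering the samples.
#' @param treatment Treatment whose flasks are screened.
#' @param top_rank Rank cutoff (default 20).
#' @param fold Fold threshold over day 0 (default 2).
#' @param fold_on_means Evaluate criterion (ii) on replicate means
#'   (default) or per flask.
#' @return Character vector of abundant feature ids, with a `detail`
#'   attribute recording which criterion each feature passed.
#' @export
abundant_asvs <- function(abund, metadata, treatment, top_rank = 20,
                          fold = 2.0, fold_on_means = TRUE) {
  md <- metadata[colnames(abund), , drop = FALSE]
  md <- md[md$treatment == treatment, , drop = FALSE]
  if (nrow(md) == 0L) bt_stop("no samples for treatment ", treatment)
  if (!any(md$day == 0L)) bt_stop("missing day 0 for treatment ", treatment)
  sub <- abund[, md$sample_id, drop = FALSE]
  days <- sort(unique(md$day))
  later <- days[days >= 1L]

  # (i) top-rank in every flask sampled on some later day
  rank_ok <- rep(FALSE, nrow(sub))
  for (d in later) {
    cols <- md$sample_id[md$day == d]
    if (length(cols) < length(unique(md$replicate))) {
      bt_log("abundant_asvs(", treatment, "): day ", d, " has only ",
             length(cols), " flask(s)")
    }
    in_top <- vapply(cols, function(s) {
      rank(-sub[, s], ties.method = "min") <= top_rank
    }, logical(nrow(sub)))
    rank_ok <- rank_ok | apply(in_top, 1L, all)
  }

  # (ii) fold increase over day 0
  day0_cols <- md$sample_id[md$day == 0L]
  if (fold_on_means) {
    base <- rowMeans(sub[, day0_cols, drop = FALSE])
    fold_ok <- rep(FALSE, nrow(sub))
    for (d in later) {
      cols <- md$sample_id[md$day == d]
      m <- rowMeans(sub[, cols, drop = FALSE])
      fold_ok <- fold_ok | (m > fold * base) | (base == 0 & m > 0)
    }
  } else {
    fold_ok <- rep(FALSE, nrow(sub))
    for (rep_ in unique(md$replicate)) {
      b_col <- md$sample_id[md$day == 0L & md$replicate == rep_]
      if (length(b_col) == 0L) next
      base <- sub[, b_col]
      for (d in later) {
        col <- md$sample_id[md$day == d & md$replicate == rep_]
        if (length(col) == 0L) next
        v <- sub[, col]
        fold_ok <- fold_ok | (v > fold * base) | (base == 0 & v > 0)
      }
    }
  }
  member <- rank_ok & fold_ok
  out <- rownames(sub)[member]
  attr(out, "detail") <- data.frame(feature_id = rownames(sub),
                                    rank_ok = rank_ok, fold_ok = fold_ok,
                                    stringsAsFactors = FALSE)
  out
}

#' Treatment-specific features from abundant sets and enrichment results
#'
#' A feature is CIF-specific (HIF-specific) if it is abundant in the CIF
#' (HIF) treatment only - in neither the control nor the other treatment -
#' and the class/subclass enrichment test calls it significantly enriched
#' in that same treatment.
#'
#' @param abundant Named list of abundant feature-id vectors, one per
#'   treatment (`control`, `CIF`, `HIF`).
#' @param lefse_res [lefse()] result with treatment classes.
#' @param kind `"ASV"` or `"vOTU"` (provenance label).
#' @return Data frame: treatment, kind, feature_id, provenance.
#' @export
treatment_specific_asvs <- function(abundant, lefse_res, kind = "ASV") {
  rows <- list()
  for (tr in c("CIF", "HIF")) {
    other <- setdiff(c("control", "CIF", "HIF"), tr)
    only <- setdiff(abundant[[tr]], unlist(abundant[other]))
    sig <- lefse_res$feature_id[lefse_res$significant &
                                  !is.na(lefse_res$enriched_class) &
                                  lefse_res$enriched_class == tr]
    members <- intersect(only, sig)
    if (length(members)) {
      rows[[tr]] <- data.frame(
        treatment = tr, kind = kind, feature_id = members,
        provenance = paste0("abundant-only-in-", tr, ";lefse-enriched-", tr),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), kind = character(0),
               feature_id = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' vOTUs that increased within one treatment
#'
#' A vOTU is called increased if the day-0-versus-later enrichment test
#' flags it significantly higher after day 0 (direction enforced) and its
#' replicate-mean approximate particle number exceeds `burst_threshold`
#' particles/mL on at least one day - below roughly one burst worth of
#' particles per mL, an apparent increase cannot reflect host lysis.
#'
#' @param pmat Particle-number matrix (vOTUs x samples) of one treatment.
#' @param metadata [sample_metadata()] covering the samples.
#' @param lefse_res [lefse()] result with classes `day0` / `after`.
#' @param burst_threshold Minimum peak particles/mL (default 100).
#' @return Character vector of increased vOTU ids with a `detail`
#'   attribute.
#' @export
increased_votus <- function(pmat, metadata, lefse_res, burst_threshold = 100) {
  md <- metadata[colnames(pmat), , drop = FALSE]
  days <- sort(unique(md$day))
  peak <- rep(-Inf, nrow(pmat))
  for (d in days) {
    cols <- md$sample_id[md$day == d]
    peak <- pmax(peak, rowMeans(pmat[, cols, drop = FALSE]))
  }
  sig <- lefse_res$significant & !is.na(lefse_res$enriched_class) &
    lefse_res$enriched_class == "after"
  sig <- sig[match(rownames(pmat), lefse_res$feature_id)]
  member <- sig & (peak > burst_threshold)
  out <- rownames(pmat)[member]
  attr(out, "detail") <- data.frame(feature_id = rownames(pmat),
                                    significant_increase = sig,
                                    peak_particles_per_ml = peak,
                                    stringsAsFactors = FALSE)
  out
}

#' Treatment-specific vOTUs from per-treatment increased sets
#'
#' CIF-specific vOTUs increased only in the CIF treatment (neither control
#' nor HIF); symmetric for HIF. vOTUs increased in both CIF and HIF but not
#' the control, and vOTUs increased in all three treatments, are reported
#' separately as fraction-associated and treatment-independent increases.
#'
#' @param increased Named list of increased vOTU-id vectors per treatment.
#' @return List with `specific` (data frame as in
#'   [treatment_specific_asvs()]), `both` and `all` (character vectors).
#' @export
treatment_specific_votus <- function(increased) {
  all3 <- Reduce(intersect, increased[c("control", "CIF", "HIF")])
  both <- setdiff(intersect(increased$CIF, increased$HIF), increased$control)
  rows <- list()
  for (tr in c("CIF", "HIF")) {
    other <- setdiff(c("control", "CIF", "HIF"), tr)
    members <- setdiff(increased[[tr]], unlist(increased[other]))
    if (length(members)) {
      rows[[tr]] <- data.frame(
        treatment = tr, kind = "vOTU", feature_id = members,
        provenance = paste0("increased-only-in-", tr),
        stringsAsFactors = FALSE)
    }
  }
  specific <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), kind = character(0),
               feature_id = character(0), provenance = character(0),
               stringsAsFactors = FALSE)
  rownames(specific) <- NULL
  list(specific = specific, both = both, all = all3)
}
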