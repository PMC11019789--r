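# Class/subclass differential-enrichment procedure: Kruskal-Wallis
# screening, subclass rank-sum consistency, and a bootstrapped
# linear-discriminant effect size. Multi-class designs are handled
# one-vs-one: a feature is enriched in a class only if it wins against
# every other class.

#' Bootstrapped linear-discriminant effect size for one feature
#'
#' Per bootstrap round a subsample (fraction `frac` of each class) is drawn,
#' a one-dimensional linear discriminant is fitted, and the absolute
#' separation of the class means on the unit discriminant axis is recorded.
#' The effect size is `log10` of the mean separation across rounds, floored
#' at 0 when the mean separation is below 1. A relative variance floor
#' (`1e-10` of the global variance) keeps the discriminant defined for
#' (near-)constant features; it never raises an error.
#'
#' @param values Numeric vector of feature values.
#' @param class_labels Two-level class label per value.
#' @param n_boot Bootstrap rounds.
#' @param frac Subsampling fraction per class and round.
#' @param seed RNG seed.
#' @return List with `score` (log10 effect size) and `enriched_class` (class
#'   with the higher mean on the full data).
#' @export
lda_effect_size <- function(values, class_labels, n_boot = 30L, frac = 2 / 3,
                            seed = NULL) {
  class_labels <- as.character(class_labels)
  classes <- unique(class_labels)
  if (length(classes) != 2L) bt_stop("lda_effect_size needs exactly 2 classes")
  if (length(values) < 4L) bt_stop("lda_effect_size needs n >= 4")
  idx1 <- which(class_labels == classes[1L])
  idx2 <- which(class_labels == classes[2L])
  floor_var <- 1e-10 * max(stats::var(values), .Machine$double.xmin)
  seps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      s1 <- idx1[sample.int(length(idx1), max(1L, ceiling(frac * length(idx1))))]
      s2 <- idx2[sample.int(length(idx2), max(1L, ceiling(frac * length(idx2))))]
      m1 <- mean(values[s1]); m2 <- mean(values[s2])
      v1 <- if (length(s1) > 1L) stats::var(values[s1]) else 0
      v2 <- if (length(s2) > 1L) stats::var(values[s2]) else 0
      sw <- max((v1 * (length(s1) - 1L) + v2 * (length(s2) - 1L)) /
                  max(1L, length(s1) + length(s2) - 2L), floor_var)
      w <- (m1 - m2) / sw           # discriminant direction (1-D)
      if (w == 0) return(0)
      axis <- sign(w)               # unit-normalised axis
      abs(axis * (m1 - m2))
    }, numeric(1))
  })
  mean_sep <- mean(seps)
  score <- if (mean_sep < 1) 0 else log10(mean_sep)
  enriched <- if (mean(values[idx1]) >= mean(values[idx2])) classes[1L] else classes[2L]
  list(score = score, enriched_class = enriched)
}

#' Direction of a rank-sum comparison between two subclasses
#' @noRd
ranksum_sign <- function(va, vb) {
  r <- midrank(c(va, vb))
  sign(mean(r[seq_along(va)]) - mean(r[-seq_along(va)]))
}

#' @noRd
lefse_one_pair <- function(values, class_labels, subclass_labels, target,
                           other, alpha, lda_threshold, n_boot, frac, seed) {
  keep <- class_labels %in% c(target, other)
  v <- values[keep]
  cl <- class_labels[keep]
  sc <- subclass_labels[keep]
  if (sum(cl == target) < 2L || sum(cl == other) < 2L) {
    bt_stop("class with < 2 samples in contrast ", target, " vs ", other)
  }
  kw <- kruskal_wallis(v, cl)
  class_sign <- sign(mean(v[cl == target]) - mean(v[cl == other]))
  consistent <- class_sign != 0
  if (consistent) {
    for (sa in unique(sc[cl == target])) {
      for (sb in unique(sc[cl == other])) {
        s <- ranksum_sign(v[cl == target & sc == sa], v[cl == other & sc == sb])
        if (s != class_sign) { consistent <- FALSE; break }
      }
      if (!consistent) break
    }
  }
  lda <- lda_effect_size(v, cl, n_boot = n_boot, frac = frac, seed = seed)
  list(kw_p = kw$p,
       consistent = consistent,
       lda_score = lda$score,
       toward_target = identical(lda$enriched_class, target) && class_sign > 0,
       significant = kw$p < alpha && consistent && lda$score >= lda_threshold)
}

#' Class/subclass differential enrichment across features
#'
#' For each feature the class with the highest overall mean is the
#' candidate; it is tested one-vs-one against every other class. A feature
#' is significant for its candidate class only if, against every other
#' class, the Kruskal-Wallis p-value is below `alpha`, every between-class
#' subclass pairwise rank-sum comparison agrees in sign with the class-level
#' difference, and the bootstrapped discriminant effect size reaches
#' `lda_threshold`.
#'
#' @param abund Abundance matrix (features x samples), absolute units.
#' @param classes Class label per sample column (e.g. treatment, or
#'   day-0/after).
#' @param subclasses Subclass label per sample column (e.g. replicate
#'   flask).
#' @param alpha Kruskal-Wallis alpha (default 0.05).
#' @param lda_threshold Minimum log10 effect size (default 2.0).
#' @param n_boot,frac Bootstrap rounds and subsampling fraction.
#' @param seed RNG seed (one deterministic sub-seed per feature).
#' @return Data frame, one row per feature: `feature_id`, `kw_p` (largest
#'   pairwise p against the candidate class), `subclass_consistent`,
#'   `lda_log_score` (smallest pairwise score), `enriched_class` (NA unless
#'   significant), `significant`.
#' @export
lefse <- function(abund, classes, subclasses, alpha = 0.05,
                  lda_threshold = 2.0, n_boot = 30L, frac = 2 / 3,
                  seed = NULL) {
  classes <- as.character(classes)
  subclasses <- as.character(subclasses)
  if (ncol(abund) != length(classes) || ncol(abund) != length(subclasses)) {
    bt_stop("classes and subclasses must label every sample column")
  }
  lv <- unique(classes)
  if (length(lv) < 2L) bt_stop("lefse needs at least 2 classes")
  if (any(table(classes) < 2L)) bt_stop("every class needs >= 2 samples")
  res <- vector("list", nrow(abund))
  for (f in seq_len(nrow(abund))) {
    v <- abund[f, ]
    cand <- lv[which.max(vapply(lv, function(c) mean(v[classes == c]), numeric(1)))]
    fseed <- if (is.null(seed)) NULL else seed + f
    pairs <- lapply(setdiff(lv, cand), function(other) {
      lefse_one_pair(v, classes, subclasses, cand, other, alpha,
                     lda_threshold, n_boot, frac, fseed)
    })
    kw_p <- max(vapply(pairs, `[[`, numeric(1), "kw_p"))
    consistent <- all(vapply(pairs, `[[`, logical(1), "consistent"))
    lda_score <- min(vapply(pairs, `[[`, numeric(1), "lda_score"))
    sig <- all(vapply(pairs, function(p) p$significant && p$toward_target,
                      logical(1)))
    res[[f]] <- data.frame(
      feature_id = rownames(abund)[f], kw_p = kw_p,
      subclass_consistent = consistent, lda_log_score = lda_score,
      enriched_class = if (sig) cand else NA_character_,
      significant = sig, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- out$feature_id
  attr(out, "seed") <- seed
  out
}
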