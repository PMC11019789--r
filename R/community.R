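# Community-structure analysis: rarefaction, Bray-Curtis dissimilarity,
# principal coordinates, ANOSIM, and phase-wise comparisons of cytometry
# totals. All primitives are implemented here directly.

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample column without replacement to exactly `depth`
#' reads; deterministic for a fixed seed. Columns already at `depth` are
#' left untouched.
#'
#' @param counts Feature count matrix (features x samples).
#' @param depth Target reads per sample.
#' @param seed RNG seed.
#' @return Rarefied count matrix; every column sums to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low)) {
    bt_stop("sample(s) below rarefaction depth ", depth, ": ",
            paste(colnames(counts)[low], collapse = ", "))
  }
  with_seed(seed, {
    out <- unclass(counts)
    for (j in seq_len(ncol(out))) {
      if (totals[j] == depth) next
      pool <- rep.int(seq_len(nrow(out)), out[, j])
      drawn <- pool[sample.int(length(pool), depth)]
      out[, j] <- tabulate(drawn, nbins = nrow(out))
    }
    feature_table(out)
  })
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x_f - y_f| / sum(x_f + y_f)` over features.
#'
#' @param counts Non-negative feature matrix (features x samples).
#' @return Symmetric samples-x-samples matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  m <- unclass(counts)
  if (any(m < 0)) bt_stop("Bray-Curtis requires non-negative abundances")
  n <- ncol(m)
  totals <- colSums(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- totals[i] + totals[j]
      if (denom == 0) {
        bt_stop("two all-zero samples: ", colnames(m)[i], ", ", colnames(m)[j])
      }
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower double-centred matrix
#' `B = -(1/2) J D^2 J`. Axes are ordered by descending eigenvalue and
#' coordinates scaled by the square root of the eigenvalue. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are dropped with a logged warning and excluded from the
#' proportion-explained denominator.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return List with `coordinates` (samples x axes), `eigenvalues`
#'   (positive, descending), `proportion_explained`, and
#'   `n_negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) bt_stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) bt_stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); gm <- mean(a)
  b <- a - outer(rm_, rm_, "+") + gm
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  neg <- eig$values < -tol
  if (any(neg)) {
    bt_log("pcoa: dropped ", sum(neg), " negative eigenvalue(s) ",
           "(non-Euclidean input)")
  }
  lambda <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), length(lambda))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(lambda))
  list(coordinates = coords,
       eigenvalues = lambda,
       proportion_explained = lambda / sum(lambda),
       n_negative_eigenvalues = sum(neg))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test for separation between groups of samples:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` dissimilarities. The permutation p-value counts the
#' observed labelling (+1/+1 convention).
#'
#' @param d Symmetric distance matrix.
#' @param grouping Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations Number of label permutations.
#' @param seed RNG seed.
#' @return List with `R`, `p`, `n_permutations`.
#' @export
anosim <- function(d, grouping, n_permutations = 999L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.character(grouping)
  if (length(grouping) != n) bt_stop("grouping length must match distance matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2L) bt_stop("anosim needs at least 2 groups")
  if (any(sizes < 2L)) {
    bt_stop("every group needs >= 2 members; offending: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  pair <- which(upper.tri(d), arr.ind = TRUE)
  rd <- midrank(d[upper.tri(d)])
  m_half <- (n * (n - 1) / 2) / 2
  r_stat <- function(g) {
    within <- g[pair[, 1L]] == g[pair[, 2L]]
    (mean(rd[!within]) - mean(rd[within])) / m_half
  }
  r_obs <- r_stat(grouping)
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      r_stat(grouping[sample.int(n)]) >= r_obs - 1e-12
    }, logical(1)))
  })
  list(R = r_obs, p = (1 + count) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Phase-wise comparison of cytometry totals between treatments
#'
#' For each incubation phase and each treatment pair, pools every
#' (replicate, day) observation of the phase per treatment and applies the
#' Mann-Whitney U test to the chosen metric; comparisons are flagged at
#' P < 0.01. Phases without observations on either side are skipped with a
#' log entry.
#'
#' @param cytometry A [cytometry_counts()] table.
#' @param metric `"cells"` (cells/mL) or `"particles"` (particles/mL).
#' @param alpha Significance level (default 0.01).
#' @return Data frame: phase, treatment pair, group sizes, U, p,
#'   significant.
#' @export
phase_compare <- function(cytometry, metric = c("cells", "particles"),
                          alpha = 0.01) {
  metric <- match.arg(metric)
  col <- if (metric == "cells") "cells_per_ml" else "particles_per_ml"
  cy <- cytometry
  cy$phase <- assign_phase(cy$day)
  treatments <- intersect(TREATMENTS, unique(cy$treatment))
  pairs <- utils::combn(treatments, 2L, simplify = FALSE)
  rows <- list()
  for (ph in c("early", "middle", "late")) {
    for (pr in pairs) {
      va <- cy[[col]][cy$phase == ph & cy$treatment == pr[1L]]
      vb <- cy[[col]][cy$phase == ph & cy$treatment == pr[2L]]
      if (length(va) == 0L || length(vb) == 0L) {
        bt_log("phase_compare: no observations for ", ph, " ",
               pr[1L], " vs ", pr[2L], "; skipped")
        next
      }
      mw <- mann_whitney_u(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, treatment_a = pr[1L], treatment_b = pr[2L],
        n_a = length(va), n_b = length(vb), U = mw$U, p = mw$p,
        significant = mw$p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Community-structure contrasts on a rarefied ASV table
#'
#' Rarefies the ASV table, computes Bray-Curtis dissimilarities and a PCoA
#' ordination, and runs the two ANOSIM contrasts of the study design:
#' early (days 0-1) versus middle-late (days 2-7) samples, and all pairwise
#' treatment contrasts among middle-late samples, with Bonferroni
#' correction over the pairwise family.
#'
#' @param ds A [bloom_dataset()].
#' @param config A [bloom_config()].
#' @return List with `ordination`, `distance`, and `anosim` (data frame of
#'   contrasts with R, p and Bonferroni-adjusted p).
#' @export
community_structure <- function(ds, config = bloom_config()) {
  rar <- rarefy(ds$counts, config$rarefaction_depth, seed = config$seed)
  d <- bray_curtis(rar)
  ord <- pcoa(d)
  md <- ds$metadata[colnames(rar), , drop = FALSE]
  rows <- list()
  grp_phase <- ifelse(md$phase == "early", "early", "middle-late")
  if (length(unique(grp_phase)) == 2L && all(table(grp_phase) >= 2L)) {
    an <- anosim(d, grp_phase, config$n_permutations, seed = config$seed)
    rows[[1L]] <- data.frame(contrast = "early vs middle-late",
                             R = an$R, p = an$p, stringsAsFactors = FALSE)
  }
  ml <- md$phase != "early"
  treatments <- intersect(TREATMENTS, unique(md$treatment[ml]))
  pair_rows <- list()
  for (pr in utils::combn(treatments, 2L, simplify = FALSE)) {
    keep <- ml & md$treatment %in% pr
    if (sum(keep) < 4L) next
    an <- anosim(d[keep, keep], md$treatment[keep], config$n_permutations,
                 seed = config$seed)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      contrast = paste("middle-late:", pr[1L], "vs", pr[2L]),
      R = an$R, p = an$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, pair_rows))
  res$p_bonferroni <- res$p
  if (length(pair_rows)) {
    is_pair <- grepl("^middle-late:", res$contrast)
    res$p_bonferroni[is_pair] <- bonferroni(res$p[is_pair])
  }
  attr(res, "seed") <- config$seed
  list(ordination = ord, distance = d, anosim = res)
}
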