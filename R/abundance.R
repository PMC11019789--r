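# Calibration of relative measures into approximate absolute abundances:
# cells/mL for ASVs via flow-cytometry cell totals, particles/mL for vOTUs
# via FPKM shares, the virus-read fraction and particle totals.

#' Relative abundance of features within each sample
#'
#' Divides each read count by the total read count of its sample.
#'
#' @param counts Feature count matrix (features x samples).
#' @return Matrix of fractions; every column sums to 1.
#' @export
#' @examples
#' m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' relative_abundance(m)
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    bt_stop("all-zero sample column(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(unclass(counts), 2L, totals, "/")
}

#' Approximate cell number of each feature
#'
#' Multiplies per-sample relative abundances by the total prokaryotic cell
#' density from flow cytometry, giving cells/mL per feature; the column sum
#' reproduces the cytometry total exactly.
#'
#' @param rel Relative-abundance matrix (features x samples), columns
#'   summing to 1.
#' @param cells_per_ml Named numeric vector of total cells/mL, one entry per
#'   sample column of `rel`.
#' @return Matrix of approximate cell numbers (cells/mL).
#' @export
approximate_cell_number <- function(rel, cells_per_ml) {
  missing <- setdiff(colnames(rel), names(cells_per_ml))
  if (length(missing)) {
    bt_stop("sample(s) without a cytometry cell total: ", paste(missing, collapse = ", "))
  }
  sweep(rel, 2L, cells_per_ml[colnames(rel)], "*")
}

#' Fragments per kilobase per million mapped reads
#'
#' @param mapped_reads Reads mapped on the contig (vectorised).
#' @param length_bp Contig length in bp (> 0).
#' @param total_mapped_reads Total mapped reads of the sample (> 0).
#' @return FPKM value(s).
#' @export
#' @examples
#' fpkm(100, 10000, 1e6) # 10
fpkm <- function(mapped_reads, length_bp, total_mapped_reads) {
  if (any(length_bp <= 0)) bt_stop("contig length must be positive")
  if (any(total_mapped_reads <= 0)) bt_stop("total mapped reads must be positive")
  if (any(mapped_reads < 0)) bt_stop("mapped reads must be non-negative")
  mapped_reads / (length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Approximate particle number of a vOTU
#'
#' The FPKM share of the vOTU among all >1 kb viral scaffolds is calibrated
#' by the fraction of viral reads among all potential virus-derived reads,
#' then scaled by the total viral particle density:
#' `P(i) = FPKM(i)/FPKM(viral) * R(viral)/(R(viral)+R(potential)) * P(viral)`.
#'
#' @param fpkm_i FPKM of the vOTU (vectorised).
#' @param fpkm_viral_total Total FPKM of >1 kb viral scaffolds (> 0).
#' @param r_viral Reads mapped on >1 kb viral scaffolds.
#' @param r_potential Potential virus-derived reads (mapped on neither host
#'   nor viral scaffolds).
#' @param particles_per_ml Total viral particle density (particles/mL).
#' @return Approximate particle number(s), particles/mL.
#' @export
#' @examples
#' approximate_particle_number(10, 100, 900, 100, 1e6) # 9e4
approximate_particle_number <- function(fpkm_i, fpkm_viral_total, r_viral,
                                        r_potential, particles_per_ml) {
  if (any(fpkm_viral_total <= 0)) {
    bt_stop("total viral FPKM must be positive (zero FPKM denominator)")
  }
  if (any(r_viral + r_potential <= 0)) {
    bt_stop("viral plus potential-viral reads must be positive (zero read denominator)")
  }
  if (any(fpkm_i < 0) || any(r_viral < 0) || any(r_potential < 0) ||
      any(particles_per_ml < 0)) {
    bt_stop("abundance inputs must be non-negative")
  }
  (fpkm_i / fpkm_viral_total) *
    (r_viral / (r_viral + r_potential)) *
    particles_per_ml
}

#' @noRd
cytometry_lookup <- function(ds, samples, what = c("cells_per_ml", "particles_per_ml")) {
  what <- match.arg(what)
  md <- ds$metadata[samples, , drop = FALSE]
  cy <- ds$cytometry
  key <- paste(md$treatment, md$replicate, md$day)
  key_cy <- paste(cy$treatment, cy$replicate, cy$day)
  idx <- match(key, key_cy)
  if (anyNA(idx)) {
    bt_stop("sample(s) without cytometry totals: ",
            paste(samples[is.na(idx)], collapse = ", "))
  }
  stats::setNames(cy[[what]][idx], samples)
}

#' Approximate cell numbers for every ASV of a dataset
#'
#' @param ds A [bloom_dataset()] with cytometry totals.
#' @return Matrix (ASVs x samples) of cells/mL.
#' @export
asv_cell_table <- function(ds) {
  if (is.null(ds$cytometry)) bt_stop("dataset has no cytometry totals")
  rel <- relative_abundance(ds$counts)
  approximate_cell_number(rel, cytometry_lookup(ds, colnames(rel), "cells_per_ml"))
}

#' Approximate particle numbers for every vOTU of a dataset
#'
#' @param ds A [bloom_dataset()] with vOTU quantification and cytometry.
#' @return Matrix (vOTUs x virome samples) of particles/mL.
#' @export
votu_particle_table <- function(ds) {
  if (is.null(ds$votu)) bt_stop("dataset has no vOTU quantification")
  if (is.null(ds$cytometry)) bt_stop("dataset has no cytometry totals")
  vq <- ds$votu
  ptot <- cytometry_lookup(ds, colnames(vq$fpkm), "particles_per_ml")
  si <- vq$sample_info
  out <- vq$fpkm
  for (j in seq_len(ncol(out))) {
    out[, j] <- approximate_particle_number(
      vq$fpkm[, j], si$fpkm_viral_total[j], si$r_viral[j], si$r_potential[j],
      ptot[j])
  }
  out
}

#' Day-level curves: replicate means of an absolute-abundance table
#'
#' Averages the per-flask values of one treatment across the replicates
#' available on each day (lost flasks reduce n, which is reported).
#'
#' @param abund Absolute-abundance matrix (features x samples).
#' @param metadata [sample_metadata()] covering the samples.
#' @param treatment Treatment to extract.
#' @return List with `mean` (features x days matrix, day labels as
#'   colnames) and `n` (replicates available per day).
#' @export
day_mean_curves <- function(abund, metadata, treatment) {
  md <- metadata[colnames(abund), , drop = FALSE]
  keep <- md$treatment == treatment
  if (!any(keep)) bt_stop("no samples for treatment ", treatment)
  md <- md[keep, , drop = FALSE]
  sub <- abund[, md$sample_id, drop = FALSE]
  days <- sort(unique(md$day))
  mean_mat <- matrix(NA_real_, nrow = nrow(sub), ncol = length(days),
                     dimnames = list(rownames(sub), as.character(days)))
  n <- stats::setNames(integer(length(days)), as.character(days))
  for (k in seq_along(days)) {
    cols <- md$sample_id[md$day == days[k]]
    n[k] <- length(cols)
    mean_mat[, k] <- rowMeans(sub[, cols, drop = FALSE])
  }
  bt_log("day means for ", treatment, ": n per day = ",
         paste(n, collapse = ","))
  list(mean = mean_mat, n = n)
}
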