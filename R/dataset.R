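#' Feature count table
#'
#' A features-by-samples matrix of non-negative integer read counts, the
#' shared container for ASV amplicon counts and vOTU mapped-read counts.
#'
#' @param counts Numeric matrix (features x samples) with unique rownames
#'   (feature ids) and colnames (sample ids); values must be non-negative
#'   integers.
#' @return The validated integer matrix, classed `feature_table`.
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) bt_stop("counts must be a matrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    bt_stop("counts must have feature ids as rownames and sample ids as colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) bt_stop("duplicate feature ids in count table")
  if (anyDuplicated(colnames(counts))) bt_stop("duplicate sample ids in count table")
  if (any(!is.finite(counts))) bt_stop("counts must be finite")
  if (any(counts < 0)) bt_stop("negative counts in feature table")
  if (any(counts != floor(counts))) bt_stop("counts must be integers")
  storage.mode(counts) <- "double"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Sample metadata table
#'
#' One row per sample: treatment, replicate flask, day (or month index for
#' environmental series) and the derived incubation phase.
#'
#' @param df Data frame with columns `sample_id`, `treatment`, `replicate`,
#'   `day`. For microcosm samples `treatment` is one of `control`, `CIF`,
#'   `HIF` and `replicate` one of `I`, `II`, `III`; environmental samples use
#'   treatment `environment` with `replicate` `NA` and `day` as month index.
#' @return Data frame with an added `phase` column, classed
#'   `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "treatment", "replicate", "day")
  if (!all(need %in% names(df))) {
    bt_stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.character(df$replicate)
  df$day <- as.integer(df$day)
  if (any(!nzchar(df$sample_id))) bt_stop("empty sample id in metadata")
  if (anyDuplicated(df$sample_id)) bt_stop("duplicate sample ids in metadata")
  env <- df$treatment == "environment"
  bad <- !env & !(df$treatment %in% TREATMENTS)
  if (any(bad)) {
    bt_stop("unknown treatment label(s): ", paste(unique(df$treatment[bad]), collapse = ", "))
  }
  if (any(!env & !(df$replicate %in% REPLICATES))) {
    bt_stop("microcosm replicate must be one of ", paste(REPLICATES, collapse = ", "))
  }
  key <- paste(df$treatment, df$replicate, df$day)
  if (anyDuplicated(key[!env])) {
    bt_stop("duplicate (treatment, replicate, day) triple in metadata")
  }
  df$phase <- NA_character_
  df$phase[!env] <- assign_phase(df$day[!env])
  rownames(df) <- df$sample_id
  class(df) <- c("sample_metadata", class(df))
  df
}

#' Parse SILVA-style semicolon-joined lineages into per-rank columns
#'
#' Accepts strings such as `"d__Bacteria; p__Bacteroidota; c__Bacteroidia"`;
#' missing tail ranks become empty strings.
#' @param lineage Character vector of semicolon-joined lineage strings.
#' @return Data frame with one column per rank (domain..genus).
#' @export
parse_silva_lineage <- function(lineage) {
  out <- matrix("", nrow = length(lineage), ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  for (i in seq_along(lineage)) {
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      hit <- which(vapply(prefixes, function(pre) startsWith(p, pre), logical(1)))
      if (length(hit) == 1L) {
        out[i, names(prefixes)[hit]] <- sub("^[dpcofg]__", "", p)
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Taxonomy table
#'
#' Ranked lineages (domain..genus) with an assignment confidence per
#' feature. Lineages may be supplied as per-rank columns or as a single
#' SILVA-style `lineage` column, which is normalized to per-rank form.
#'
#' @param df Data frame with `feature_id`, either a `lineage` column or the
#'   rank columns `domain`..`genus`, and `confidence` in `[0, 1]`.
#' @return Per-rank data frame classed `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) bt_stop("taxonomy needs a feature_id column")
  if ("lineage" %in% names(df) && !all(TAXONOMY_RANKS %in% names(df))) {
    df <- cbind(df[, "feature_id", drop = FALSE],
                parse_silva_lineage(df$lineage),
                confidence = df$confidence)
  }
  if (!all(TAXONOMY_RANKS %in% names(df))) {
    bt_stop("taxonomy needs rank columns: ", paste(TAXONOMY_RANKS, collapse = ", "))
  }
  if (!"confidence" %in% names(df)) bt_stop("taxonomy needs a confidence column")
  df$confidence <- as.numeric(df$confidence)
  if (any(!is.finite(df$confidence)) || any(df$confidence < 0 | df$confidence > 1)) {
    bt_stop("taxonomy confidence must lie in [0, 1]")
  }
  if (anyDuplicated(df$feature_id)) bt_stop("duplicate feature ids in taxonomy")
  for (r in TAXONOMY_RANKS) df[[r]] <- ifelse(is.na(df[[r]]), "", as.character(df[[r]]))
  # ordered ranks: a named rank must not follow an empty coarser rank
  filled <- as.matrix(df[TAXONOMY_RANKS]) != ""
  if (nrow(df) > 0) {
    gap <- apply(filled, 1L, function(z) any(diff(as.integer(z)) > 0L))
    if (any(gap)) {
      bt_stop("taxonomy lineage has a named rank below an empty rank for: ",
              paste(df$feature_id[gap], collapse = ", "))
    }
  }
  df <- df[, c("feature_id", TAXONOMY_RANKS, "confidence")]
  rownames(df) <- df$feature_id
  class(df) <- c("taxonomy_table", class(df))
  df
}

#' Flow-cytometry totals
#'
#' Per (treatment, replicate, day): total prokaryotic cells/mL and total
#' viral particles/mL, the absolute denominators of the calibration.
#'
#' @param df Data frame with columns `treatment`, `replicate`, `day`,
#'   `cells_per_ml`, `particles_per_ml`.
#' @return Validated data frame classed `cytometry_counts`.
#' @export
cytometry_counts <- function(df) {
  need <- c("treatment", "replicate", "day", "cells_per_ml", "particles_per_ml")
  if (!all(need %in% names(df))) {
    bt_stop("cytometry must have columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$day <- as.integer(df$day)
  for (col in c("cells_per_ml", "particles_per_ml")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      bt_stop("cytometry ", col, " must be non-negative and finite")
    }
  }
  if (any(!(df$treatment %in% TREATMENTS))) {
    bt_stop("unknown treatment label in cytometry: ",
            paste(setdiff(unique(df$treatment), TREATMENTS), collapse = ", "))
  }
  if (anyDuplicated(paste(df$treatment, df$replicate, df$day))) {
    bt_stop("duplicate (treatment, replicate, day) in cytometry")
  }
  class(df) <- c("cytometry_counts", class(df))
  df
}

#' vOTU quantification bundle
#'
#' Per-sample vOTU FPKM values with contig lengths and the per-sample
#' denominators of the particle calibration: total FPKM of >1 kb viral
#' scaffolds, reads mapped on viral scaffolds and potential virus-derived
#' reads (mapped on neither host nor viral scaffolds).
#'
#' @param fpkm Numeric matrix (vOTUs x samples) of FPKM values.
#' @param length_bp Named integer vector of vOTU contig lengths (bp).
#' @param sample_info Data frame with columns `sample_id`,
#'   `fpkm_viral_total`, `r_viral`, `r_potential`.
#' @return List classed `votu_quant`.
#' @export
votu_quant <- function(fpkm, length_bp, sample_info) {
  if (!is.matrix(fpkm) || is.null(rownames(fpkm)) || is.null(colnames(fpkm))) {
    bt_stop("fpkm must be a matrix with vOTU rownames and sample colnames")
  }
  if (any(!is.finite(fpkm)) || any(fpkm < 0)) bt_stop("fpkm values must be non-negative")
  if (anyDuplicated(rownames(fpkm))) bt_stop("duplicate vOTU ids in fpkm table")
  missing_len <- setdiff(rownames(fpkm), names(length_bp))
  if (length(missing_len)) {
    bt_stop("vOTU(s) without contig length: ", paste(missing_len, collapse = ", "))
  }
  length_bp <- length_bp[rownames(fpkm)]
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    bt_stop("contig lengths must be positive")
  }
  need <- c("sample_id", "fpkm_viral_total", "r_viral", "r_potential")
  if (!all(need %in% names(sample_info))) {
    bt_stop("votu sample_info must have columns: ", paste(need, collapse = ", "))
  }
  sample_info <- as.data.frame(sample_info, stringsAsFactors = FALSE)
  rownames(sample_info) <- sample_info$sample_id
  missing_den <- setdiff(colnames(fpkm), sample_info$sample_id)
  if (length(missing_den)) {
    bt_stop("virome sample(s) without denominators: ", paste(missing_den, collapse = ", "))
  }
  sample_info <- sample_info[colnames(fpkm), , drop = FALSE]
  for (col in c("fpkm_viral_total", "r_viral", "r_potential")) {
    sample_info[[col]] <- as.numeric(sample_info[[col]])
    if (any(!is.finite(sample_info[[col]])) || any(sample_info[[col]] < 0)) {
      bt_stop("votu denominator ", col, " must be non-negative")
    }
  }
  # catalogued >10 kb vOTUs are a subset of all >1 kb viral scaffolds, so
  # their FPKM cannot exceed the total viral FPKM (small numerical slack)
  over <- colSums(fpkm) > sample_info$fpkm_viral_total * (1 + 1e-9)
  if (any(over)) {
    bt_stop("sum of vOTU FPKM exceeds fpkm_viral_total in sample(s): ",
            paste(colnames(fpkm)[over], collapse = ", "))
  }
  structure(list(fpkm = fpkm, length_bp = length_bp, sample_info = sample_info),
            class = "votu_quant")
}

#' Host predictions for vOTUs
#'
#' @param df Data frame with columns `votu_id`, `host_rank` (one of
#'   domain..genus, or empty when unknown), `host_taxon` (empty when
#'   unknown), `gotu`, `lysogenic` (logical).
#' @return Validated data frame classed `host_prediction`.
#' @export
host_prediction <- function(df) {
  need <- c("votu_id", "host_rank", "host_taxon", "gotu", "lysogenic")
  if (!all(need %in% names(df))) {
    bt_stop("host predictions must have columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$host_rank <- ifelse(is.na(df$host_rank), "", as.character(df$host_rank))
  df$host_taxon <- ifelse(is.na(df$host_taxon), "", as.character(df$host_taxon))
  df$lysogenic <- as.logical(df$lysogenic)
  known <- nzchar(df$host_taxon)
  bad_rank <- known & !(df$host_rank %in% TAXONOMY_RANKS)
  if (any(bad_rank)) {
    bt_stop("host rank must be one of ", paste(TAXONOMY_RANKS, collapse = ", "),
            " (no finer than genus); offending vOTU(s): ",
            paste(df$votu_id[bad_rank], collapse = ", "))
  }
  if (anyDuplicated(df$votu_id)) bt_stop("duplicate vOTU ids in host predictions")
  rownames(df) <- df$votu_id
  class(df) <- c("host_prediction", class(df))
  df
}

#' Assemble and cross-validate a full microcosm dataset bundle
#'
#' @param counts ASV [feature_table()] (features x samples).
#' @param metadata [sample_metadata()] covering amplicon and virome samples.
#' @param taxonomy [taxonomy_table()] for the ASVs.
#' @param cytometry [cytometry_counts()] totals.
#' @param votu [votu_quant()] bundle (optional, `NULL` for amplicon-only).
#' @param host [host_prediction()] table (optional).
#' @return List classed `bloom_dataset` with a `validation` attribute
#'   summarising the checks performed.
#' @export
bloom_dataset <- function(counts, metadata, taxonomy = NULL, cytometry = NULL,
                          votu = NULL, host = NULL) {
  counts <- if (inherits(counts, "feature_table")) counts else feature_table(counts)
  metadata <- if (inherits(metadata, "sample_metadata")) metadata else sample_metadata(metadata)
  errs <- character(0)
  orphan <- setdiff(colnames(counts), metadata$sample_id)
  if (length(orphan)) {
    bt_stop("sample(s) in feature table missing from metadata: ",
            paste(orphan, collapse = ", "))
  }
  if (!is.null(taxonomy)) {
    taxonomy <- if (inherits(taxonomy, "taxonomy_table")) taxonomy else taxonomy_table(taxonomy)
    untaxed <- setdiff(rownames(counts), taxonomy$feature_id)
    if (length(untaxed)) {
      errs <- c(errs, paste0(length(untaxed), " ASV(s) without taxonomy"))
    }
  }
  if (!is.null(cytometry)) {
    cytometry <- if (inherits(cytometry, "cytometry_counts")) cytometry else cytometry_counts(cytometry)
    md <- metadata[metadata$treatment != "environment", , drop = FALSE]
    key_md <- paste(md$treatment, md$replicate, md$day)
    key_cy <- paste(cytometry$treatment, cytometry$replicate, cytometry$day)
    nocyt <- setdiff(key_md, key_cy)
    if (length(nocyt)) {
      bt_stop("sample(s) without cytometry totals: ", paste(nocyt, collapse = "; "))
    }
  }
  if (!is.null(votu)) {
    if (!inherits(votu, "votu_quant")) bt_stop("votu must be a votu_quant object")
    orphan_v <- setdiff(colnames(votu$fpkm), metadata$sample_id)
    if (length(orphan_v)) {
      bt_stop("virome sample(s) missing from metadata: ", paste(orphan_v, collapse = ", "))
    }
  }
  if (!is.null(host)) {
    host <- if (inherits(host, "host_prediction")) host else host_prediction(host)
  }
  ds <- structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                       cytometry = cytometry, votu = votu, host = host),
                  class = "bloom_dataset")
  attr(ds, "validation") <- sprintf(
    "%d samples, %d ASVs, %d vOTUs, %d errors",
    ncol(counts), nrow(counts),
    if (is.null(votu)) 0L else nrow(votu$fpkm), length(errs))
  if (length(errs)) attr(ds, "validation_warnings") <- errs
  bt_log("dataset validated: ", attr(ds, "validation"))
  ds
}

#' @export
print.bloom_dataset <- function(x, ...) {
  cat("bloom_dataset:", attr(x, "validation"), "\n")
  tr <- table(x$metadata$treatment)
  cat("  samples per treatment:",
      paste(names(tr), tr, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
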