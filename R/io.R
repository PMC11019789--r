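# TSV dialect: header row, UTF-8, tab-separated, ids in the first column.
# "#"-prefixed lines are comments (used to record the RNG seed of generated
# outputs). Missing counts are written as 0; empty taxonomy tail ranks as
# explicit empty strings, never ".".

#' @noRd
write_bt_tsv <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", format(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' @noRd
read_bt_tsv <- function(path, ...) {
  if (!file.exists(path)) bt_stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8", ...)
}

#' Write a feature count table to TSV
#'
#' First column `feature_id`, one column per sample. Reading the file back
#' with [read_feature_table()] restores the table exactly.
#' @param x Feature count matrix ([feature_table()]).
#' @param path Output path.
#' @param seed Optional seed to record as a header comment.
#' @export
write_feature_table <- function(x, path, seed = NULL) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write_bt_tsv(df, path, seed)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_bt_tsv(path)
  if (ncol(df) < 1L) bt_stop("feature table has no columns: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  rownames(m) <- ids
  feature_table(m)
}

#' Write/read sample metadata
#' @param x A [sample_metadata()] data frame.
#' @inheritParams write_feature_table
#' @export
write_sample_metadata <- function(x, path, seed = NULL) {
  write_bt_tsv(x[, c("sample_id", "treatment", "replicate", "day", "phase")],
               path, seed)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  df <- read_bt_tsv(path)
  df$replicate[!nzchar(df$replicate)] <- NA_character_
  sample_metadata(df[, c("sample_id", "treatment", "replicate", "day")])
}

#' Write/read taxonomy
#' @param x A [taxonomy_table()].
#' @inheritParams write_feature_table
#' @export
write_taxonomy <- function(x, path, seed = NULL) write_bt_tsv(x, path, seed)

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) taxonomy_table(read_bt_tsv(path))

#' Write/read flow-cytometry totals
#' @param x A [cytometry_counts()] table.
#' @inheritParams write_feature_table
#' @export
write_cytometry <- function(x, path, seed = NULL) write_bt_tsv(x, path, seed)

#' @rdname write_cytometry
#' @export
read_cytometry <- function(path) cytometry_counts(read_bt_tsv(path))

#' Write/read the vOTU quantification bundle
#'
#' Long format: one row per (vOTU, sample) with the contig length and the
#' per-sample calibration denominators repeated on each row; denominators
#' must agree across rows of the same sample.
#' @param x A [votu_quant()] bundle.
#' @inheritParams write_feature_table
#' @export
write_votu_quant <- function(x, path, seed = NULL) {
  long <- expand.grid(votu_id = rownames(x$fpkm), sample_id = colnames(x$fpkm),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$length_bp <- x$length_bp[long$votu_id]
  long$fpkm <- as.vector(x$fpkm)
  si <- x$sample_info[long$sample_id, , drop = FALSE]
  long$fpkm_viral_total <- si$fpkm_viral_total
  long$r_viral <- si$r_viral
  long$r_potential <- si$r_potential
  write_bt_tsv(long, path, seed)
}

#' @rdname write_votu_quant
#' @export
read_votu_quant <- function(path) {
  df <- read_bt_tsv(path)
  need <- c("votu_id", "sample_id", "length_bp", "fpkm", "fpkm_viral_total",
            "r_viral", "r_potential")
  if (!all(need %in% names(df))) {
    bt_stop("votu_quant file must have columns: ", paste(need, collapse = ", "))
  }
  votus <- unique(df$votu_id)
  samples <- unique(df$sample_id)
  fpkm <- matrix(0, nrow = length(votus), ncol = length(samples),
                 dimnames = list(votus, samples))
  fpkm[cbind(match(df$votu_id, votus), match(df$sample_id, samples))] <- df$fpkm
  len <- tapply(df$length_bp, df$votu_id, function(v) v[1L])[votus]
  for (col in c("fpkm_viral_total", "r_viral", "r_potential")) {
    spread <- tapply(df[[col]], df$sample_id, function(v) diff(range(v)))
    if (any(spread > 0)) {
      bt_stop("inconsistent ", col, " across rows of the same sample in ", path)
    }
  }
  first <- !duplicated(df$sample_id)
  si <- df[first, c("sample_id", "fpkm_viral_total", "r_viral", "r_potential")]
  votu_quant(fpkm, len, si)
}

#' Write/read host predictions
#' @param x A [host_prediction()] table.
#' @inheritParams write_feature_table
#' @export
write_host_prediction <- function(x, path, seed = NULL) write_bt_tsv(x, path, seed)

#' @rdname write_host_prediction
#' @export
read_host_prediction <- function(path) {
  df <- read_bt_tsv(path)
  df$lysogenic <- as.logical(df$lysogenic)
  host_prediction(df)
}

#' Environmental time series of ASV and vOTU abundances
#'
#' Monthly abundances at the sampling site: read-mapping-derived relative
#' abundance for ASVs and FPKM for vOTUs, over the same time points. Because
#' both are derived by mapping against a fixed set of features of interest,
#' neither is closed to a constant sum.
#'
#' @param asv Numeric matrix (ASVs x time points) of relative abundances.
#' @param votu Numeric matrix (vOTUs x time points) of FPKM values, same
#'   column names as `asv`.
#' @return List classed `env_series`.
#' @export
env_series <- function(asv, votu) {
  if (!is.matrix(asv) || !is.matrix(votu)) bt_stop("env series parts must be matrices")
  if (is.null(colnames(asv)) || !identical(colnames(asv), colnames(votu))) {
    bt_stop("ASV and vOTU series must share identical time-point columns")
  }
  if (any(!is.finite(asv)) || any(asv < 0) || any(!is.finite(votu)) || any(votu < 0)) {
    bt_stop("environmental abundances must be non-negative")
  }
  structure(list(asv = asv, votu = votu), class = "env_series")
}

#' @rdname env_series
#' @param x An `env_series` object.
#' @inheritParams write_feature_table
#' @export
write_env_series <- function(x, path, seed = NULL) {
  df <- data.frame(feature_id = c(rownames(x$asv), rownames(x$votu)),
                   kind = rep(c("ASV", "vOTU"), c(nrow(x$asv), nrow(x$votu))),
                   rbind(as.data.frame(x$asv), as.data.frame(x$votu)),
                   check.names = FALSE)
  write_bt_tsv(df, path, seed)
}

#' @rdname env_series
#' @export
read_env_series <- function(path) {
  df <- read_bt_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), c("feature_id", "kind")), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  env_series(m[df$kind == "ASV", , drop = FALSE],
             m[df$kind == "vOTU", , drop = FALSE])
}

#' Load and cross-validate a full input bundle from TSV files
#'
#' Samples whose amplicon read total falls below
#' `config$min_reads_amplicon`, or whose virome read total (viral plus
#' potential-viral reads) falls below `config$min_reads_virome`, are dropped
#' and logged rather than erroring: lost or shallow samples are an expected
#' feature of real microcosm data.
#'
#' @param feature_table_path,metadata_path,taxonomy_path,cytometry_path
#'   Paths to the ASV table, metadata, taxonomy, and cytometry TSVs.
#' @param votu_quant_path,host_pred_path Optional paths to the vOTU
#'   quantification and host-prediction TSVs (`NULL` to omit the virome).
#' @param config A [bloom_config()].
#' @return A validated [bloom_dataset()]; dropped samples are recorded in
#'   the `dropped_samples` attribute.
#' @export
load_dataset <- function(feature_table_path, metadata_path, taxonomy_path = NULL,
                         cytometry_path = NULL, votu_quant_path = NULL,
                         host_pred_path = NULL, config = bloom_config()) {
  counts <- read_feature_table(feature_table_path)
  metadata <- read_sample_metadata(metadata_path)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  cytometry <- if (!is.null(cytometry_path)) read_cytometry(cytometry_path)
  votu <- if (!is.null(votu_quant_path)) read_votu_quant(votu_quant_path)
  host <- if (!is.null(host_pred_path)) read_host_prediction(host_pred_path)

  dropped <- character(0)
  shallow <- colnames(counts)[colSums(counts) < config$min_reads_amplicon]
  if (length(shallow)) {
    bt_log("dropping ", length(shallow), " amplicon sample(s) under ",
           config$min_reads_amplicon, " reads: ", paste(shallow, collapse = ", "))
    counts <- feature_table(counts[, setdiff(colnames(counts), shallow), drop = FALSE])
    dropped <- c(dropped, shallow)
  }
  if (!is.null(votu)) {
    vtot <- votu$sample_info$r_viral + votu$sample_info$r_potential
    shallow_v <- colnames(votu$fpkm)[vtot < config$min_reads_virome]
    if (length(shallow_v)) {
      bt_log("dropping ", length(shallow_v), " virome sample(s) under ",
             config$min_reads_virome, " reads: ", paste(shallow_v, collapse = ", "))
      keep <- setdiff(colnames(votu$fpkm), shallow_v)
      votu <- votu_quant(votu$fpkm[, keep, drop = FALSE], votu$length_bp,
                         votu$sample_info[keep, , drop = FALSE])
      dropped <- c(dropped, shallow_v)
    }
  }
  ds <- bloom_dataset(counts, metadata, taxonomy, cytometry, votu, host)
  attr(ds, "dropped_samples") <- dropped
  ds
}

#' Write a full dataset bundle to a directory of TSV files
#'
#' @param ds A [bloom_dataset()].
#' @param dir Output directory (created if absent).
#' @param seed Optional seed recorded in every file header.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(ds$counts, file.path(dir, "feature_table.tsv"), seed)
  write_sample_metadata(ds$metadata, file.path(dir, "metadata.tsv"), seed)
  if (!is.null(ds$taxonomy)) write_taxonomy(ds$taxonomy, file.path(dir, "taxonomy.tsv"), seed)
  if (!is.null(ds$cytometry)) write_cytometry(ds$cytometry, file.path(dir, "cytometry.tsv"), seed)
  if (!is.null(ds$votu)) write_votu_quant(ds$votu, file.path(dir, "votu_quant.tsv"), seed)
  if (!is.null(ds$host)) write_host_prediction(ds$host, file.path(dir, "host_predictions.tsv"), seed)
  invisible(dir)
}
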