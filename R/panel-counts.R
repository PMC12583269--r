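#' Raw panel counts container
#'
#' Bundles a samples-by-genes matrix of raw read counts from a targeted RNA
#' panel with its batch structure: every sample belongs to a sequencing batch
#' and every batch carries one no-template-control (NTC) count vector that
#' estimates per-gene background signal for that batch.
#'
#' @param counts integer matrix, samples in rows, genes in columns; rownames
#'   are sample ids, colnames gene ids. All entries must be non-negative.
#' @param batch character vector, one batch label per sample (named by sample
#'   id or in row order).
#' @param ntc numeric matrix of NTC counts, one row per batch (rownames are
#'   batch labels), columns matching `counts` columns.
#' @return An object of class `panel_counts`.
#' @export
panel_counts <- function(counts, batch, ntc) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have sample rownames and gene colnames")
  if (any(counts < 0) || any(!is.finite(counts)))
    stopf("counts must be finite and non-negative")
  if (is.null(names(batch))) {
    if (length(batch) != nrow(counts))
      stopf("batch must have one entry per sample")
    names(batch) <- rownames(counts)
  }
  batch <- batch[rownames(counts)]
  if (anyNA(batch)) stopf("every sample needs a batch label")
  ntc <- as.matrix(ntc)
  if (!setequal(colnames(ntc), colnames(counts)))
    stopf("NTC genes must match count matrix genes")
  ntc <- ntc[, colnames(counts), drop = FALSE]
  missing_b <- setdiff(unique(batch), rownames(ntc))
  if (length(missing_b))
    stopf("batches without an NTC row: %s", paste(missing_b, collapse = ", "))
  if (any(ntc < 0)) stopf("NTC counts must be non-negative")
  structure(
    list(counts = counts, batch = batch, ntc = ntc,
         sample_ids = rownames(counts), gene_ids = colnames(counts)),
    class = "panel_counts")
}

#' @export
print.panel_counts <- function(x, ...) {
  cat(sprintf("panel_counts: %d samples x %d genes, %d batch(es)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$batch))))
  invisible(x)
}

#' @export
dim.panel_counts <- function(x) dim(x$counts)

#' Reference model for percentile ranking
#'
#' A locked reference model holds (i) the stable housekeeping (HK) RPM
#' profile against which each sample's HK RPMs are compared to form the
#' sample-specific Normalization Ratio, and (ii) per-gene sorted nRPM
#' distributions from the reference cohort, against which study samples are
#' percentile-ranked.
#'
#' @param hk_genes character vector of exactly 10 housekeeping gene ids.
#' @param hk_rpm_profile named positive numeric, reference RPM per HK gene.
#' @param reference_nrpm named list of numeric vectors (one per panel gene),
#'   each the reference cohort's nRPM values; stored sorted ascending.
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(hk_genes, hk_rpm_profile, reference_nrpm) {
  if (length(hk_genes) != 10L)
    stopf("expected exactly 10 housekeeping genes, got %d", length(hk_genes))
  if (!all(hk_genes %in% names(hk_rpm_profile)))
    stopf("hk_rpm_profile must cover all housekeeping genes")
  hk_rpm_profile <- hk_rpm_profile[hk_genes]
  if (any(hk_rpm_profile <= 0))
    stopf("housekeeping RPM profile values must be positive")
  sizes <- lengths(reference_nrpm)
  if (length(unique(sizes)) != 1L)
    stopf("all reference nRPM vectors must have equal length")
  reference_nrpm <- lapply(reference_nrpm, sort)
  degenerate <- names(reference_nrpm)[
    vapply(reference_nrpm, function(v) length(unique(v)) < 2L, logical(1))]
  if (length(degenerate))
    stopf("degenerate reference: fewer than 2 distinct nRPM values for %s",
          paste(degenerate, collapse = ", "))
  structure(
    list(hk_genes = hk_genes, hk_rpm_profile = hk_rpm_profile,
         reference_nrpm = reference_nrpm, reference_size = sizes[[1]]),
    class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "reference_model: %d reference samples, %d genes, %d HK genes\n",
    x$reference_size, length(x$reference_nrpm), length(x$hk_genes)))
  invisible(x)
}
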