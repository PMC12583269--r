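#' Background-subtract a sample against its batch NTC
#'
#' Per-gene subtraction of the no-template-control counts from a sample's
#' raw counts, floored at zero: reads at or below the NTC level are treated
#' as background signal.
#'
#' @param sample_counts non-negative numeric vector of raw counts.
#' @param ntc_counts non-negative numeric vector of NTC counts for the same
#'   genes, in the same order.
#' @return Adjusted count vector, `pmax(sample - ntc, 0)`.
#' @export
subtract_background <- function(sample_counts, ntc_counts) {
  if (length(sample_counts) != length(ntc_counts))
    stopf("sample and NTC vectors differ in length (%d vs %d)",
          length(sample_counts), length(ntc_counts))
  if (any(sample_counts < 0) || any(ntc_counts < 0))
    stopf("counts must be non-negative")
  pmax(sample_counts - ntc_counts, 0)
}

#' Convert adjusted counts to reads per million
#'
#' @param adjusted non-negative numeric vector of background-subtracted
#'   counts.
#' @return RPM vector summing to 1e6.
#' @export
to_rpm <- function(adjusted) {
  if (any(adjusted < 0)) stopf("adjusted counts must be non-negative")
  total <- sum(adjusted)
  if (total <= 0) stopf("zero-depth sample: no reads after background subtraction")
  adjusted * 1e6 / total
}

#' Sample-specific housekeeping Normalization Ratio
#'
#' The median, over housekeeping genes, of the ratio between the sample's HK
#' RPM and the locked reference HK RPM profile. For an even number of HK
#' genes the median is the mean of the two central ratios.
#'
#' @param sample_hk_rpm named numeric, the sample's RPM for the HK genes.
#' @param hk_rpm_profile named positive numeric, the reference HK profile.
#' @return Positive scalar Normalization Ratio.
#' @export
normalization_ratio <- function(sample_hk_rpm, hk_rpm_profile) {
  genes <- names(hk_rpm_profile)
  if (is.null(genes)) stopf("hk_rpm_profile must be named by gene")
  usable <- genes[hk_rpm_profile[genes] > 0]
  if (!length(usable)) stopf("no housekeeping gene has a positive profile value")
  if (!all(usable %in% names(sample_hk_rpm)))
    stopf("sample is missing housekeeping genes: %s",
          paste(setdiff(usable, names(sample_hk_rpm)), collapse = ", "))
  ratios <- sample_hk_rpm[usable] / hk_rpm_profile[usable]
  if (all(ratios == 0))
    stopf("QC failure: all housekeeping RPMs are zero in this sample")
  ratio <- median(ratios)
  if (ratio <= 0)
    stopf("QC failure: non-positive housekeeping Normalization Ratio")
  unname(ratio)
}

#' Compute nRPM for every sample in a panel
#'
#' Chains background subtraction (against each sample's batch NTC), RPM
#' conversion, and division by the sample-specific housekeeping
#' Normalization Ratio. The default numerator is RPM, making nRPM invariant
#' to sequencing depth; `numerator = "reads"` divides raw
#' background-subtracted counts instead, for sensitivity analyses.
#'
#' @param panel a [panel_counts()] object.
#' @param model a [reference_model()] (only its HK genes/profile are used).
#' @param numerator `"rpm"` (default) or `"reads"`.
#' @return Numeric matrix of nRPM, samples x genes, with attribute
#'   `qc_failed` listing samples excluded for zero depth or zero HK signal.
#' @export
compute_nrpm <- function(panel, model, numerator = c("rpm", "reads")) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(panel, "panel_counts"), inherits(model, "reference_model"))
  missing_hk <- setdiff(model$hk_genes, panel$gene_ids)
  if (length(missing_hk))
    stopf("panel lacks housekeeping genes: %s", paste(missing_hk, collapse = ", "))
  out <- matrix(NA_real_, nrow(panel$counts), ncol(panel$counts),
                dimnames = dimnames(panel$counts))
  qc_failed <- character(0)
  for (s in panel$sample_ids) {
    adj <- subtract_background(panel$counts[s, ], panel$ntc[panel$batch[[s]], ])
    res <- tryCatch({
      rpm <- to_rpm(adj)
      ratio <- normalization_ratio(rpm[model$hk_genes], model$hk_rpm_profile)
      if (numerator == "rpm") rpm / ratio else adj / ratio
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc_failed <- c(qc_failed, s)
    } else {
      out[s, ] <- res
    }
  }
  if (length(qc_failed)) {
    warnf("QC-failed samples excluded from nRPM: %s",
          paste(qc_failed, collapse = ", "))
    out <- out[setdiff(rownames(out), qc_failed), , drop = FALSE]
  }
  attr(out, "qc_failed") <- qc_failed
  out
}

#' Percentile rank of values within a reference distribution
#'
#' Mid-rank convention: `rank = 100 * (#\{r < v\} + 0.5 * #\{r = v\}) / N`,
#' giving values in [0, 100] that are non-decreasing in `v` and symmetric in
#' how ties with reference values are split.
#'
#' @param value numeric vector of query values.
#' @param reference numeric vector, the reference distribution (any order).
#' @return Numeric vector of ranks in [0, 100].
#' @export
percentile_rank <- function(value, reference) {
  if (!length(reference)) stopf("empty reference distribution")
  r <- sort(reference)
  n_lt <- findInterval(value, r, left.open = TRUE)
  n_le <- findInterval(value, r)
  100 * (n_lt + 0.5 * (n_le - n_lt)) / length(r)
}

#' Three-level expression category from a percentile rank
#'
#' high: rank >= 75; moderate: 25 <= rank < 75; low: rank < 25.
#'
#' @param rank numeric vector of percentile ranks in [0, 100].
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
categorize <- function(rank) {
  if (any(rank < 0 | rank > 100, na.rm = TRUE))
    stopf("ranks must lie in [0, 100]")
  out <- ifelse(rank >= 75, "high", ifelse(rank >= 25, "moderate", "low"))
  factor(out, levels = c("low", "moderate", "high"))
}

#' Build a locked reference model from a reference cohort
#'
#' The HK RPM profile is the per-housekeeping-gene median RPM across
#' reference samples (computed on background-subtracted counts). Reference
#' nRPM distributions are then computed for every panel gene by normalizing
#' the reference cohort itself against that profile.
#'
#' @param panel a [panel_counts()] object for the reference cohort.
#' @param hk_genes character vector of the 10 housekeeping gene ids.
#' @return A [reference_model()].
#' @export
build_reference_model <- function(panel, hk_genes) {
  stopifnot(inherits(panel, "panel_counts"))
  if (nrow(panel$counts) < 10L)
    stopf("reference cohort needs at least 10 samples")
  rpm <- t(vapply(panel$sample_ids, function(s) {
    to_rpm(subtract_background(panel$counts[s, ], panel$ntc[panel$batch[[s]], ]))
  }, numeric(ncol(panel$counts))))
  colnames(rpm) <- panel$gene_ids
  profile <- apply(rpm[, hk_genes, drop = FALSE], 2, median)
  # provisional model carrying the profile; reference distributions follow
  ratios <- apply(rpm[, hk_genes, drop = FALSE], 1,
                  function(x) median(x / profile))
  nrpm <- sweep(rpm, 1, ratios, "/")
  reference_model(
    hk_genes = hk_genes,
    hk_rpm_profile = profile,
    reference_nrpm = lapply(setNames(panel$gene_ids, panel$gene_ids),
                            function(g) sort(unname(nrpm[, g]))))
}

#' Rank a cohort against a reference model
#'
#' Computes nRPM for every sample, percentile-ranks each gene's nRPM within
#' the reference distribution, and assigns low/moderate/high categories.
#'
#' @param panel a [panel_counts()] object.
#' @param model a [reference_model()].
#' @param numerator passed to [compute_nrpm()].
#' @return Long data frame with columns `sample_id`, `gene`, `nrpm`, `rank`,
#'   `category`.
#' @export
rank_cohort <- function(panel, model, numerator = "rpm") {
  nrpm <- compute_nrpm(panel, model, numerator = numerator)
  genes <- intersect(colnames(nrpm), names(model$reference_nrpm))
  res <- do.call(rbind, lapply(genes, function(g) {
    rk <- percentile_rank(nrpm[, g], model$reference_nrpm[[g]])
    data.frame(sample_id = rownames(nrpm), gene = g,
               nrpm = unname(nrpm[, g]), rank = rk,
               category = categorize(rk),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(res, "qc_failed") <- attr(nrpm, "qc_failed")
  res
}
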