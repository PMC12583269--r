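# Somatic-mutation enrichment between expression groups: Fisher's exact
# test per gene and per hallmark pathway, Benjamini-Hochberg q-values, the
# q < 0.05 & |log2 OR| > 1 significance rule, and the Bonferroni-corrected
# top-k frequently-altered-gene comparison.

#' Two-sided Fisher exact test with cross-product odds ratio
#'
#' The p-value sums hypergeometric probabilities of all tables (with the
#' observed margins) whose probability does not exceed that of the
#' observed table (relative tie tolerance 1e-7). The odds ratio is the
#' sample cross-product `(a*d)/(b*c)`, with the Haldane-Anscombe +0.5
#' correction (flagged) when any cell is zero. A zero margin yields p = 1
#' and an undefined odds ratio.
#'
#' @param a,b,c,d non-negative integer cell counts (rows: group; columns:
#'   altered / not altered).
#' @return List with `p_value`, `odds_ratio`, `log2_or`, `corrected`,
#'   `or_defined`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  if (sum(cells) == 0) stopf("empty table")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = NA_real_, log2_or = NA_real_,
                corrected = FALSE, or_defined = FALSE))
  m <- a + b          # row-1 margin
  k <- a + c          # column-1 margin
  n_tot <- sum(cells)
  lo <- max(0L, k - (n_tot - m)); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n_tot - m, k)
  p_obs <- dhyper(a, m, n_tot - m, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  list(p_value = p, odds_ratio = or, log2_or = log2(or),
       corrected = corrected, or_defined = TRUE)
}

enrichment_rows <- function(mat, group, level, min_altered) {
  group <- as.logical(group)
  if (length(group) != nrow(mat))
    stopf("group length must match the number of samples")
  if (!any(group) || !any(!group))
    stopf("both groups must be non-empty")
  keep <- colSums(mat) >= min_altered
  if (!any(keep)) stopf("no feature passes the min_altered filter")
  feats <- colnames(mat)[keep]
  n1 <- sum(group); n2 <- sum(!group)
  rows <- lapply(feats, function(f) {
    a <- sum(mat[group, f]); c_ <- sum(mat[!group, f])
    fe <- fisher_exact_2x2(a, n1 - a, c_, n2 - c_)
    data.frame(feature = f, level = level,
               altered_high = a, total_high = n1,
               altered_ref = c_, total_ref = n2,
               odds_ratio = fe$odds_ratio, log2_or = fe$log2_or,
               p_value = fe$p_value, corrected = fe$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$q_value < 0.05 & abs(out$log2_or) > 1
  out$direction <- ifelse(out$log2_or > 0, "high", "low_moderate")
  rownames(out) <- NULL
  out
}

#' Gene-level mutation enrichment between expression groups
#'
#' Per gene altered in at least `min_altered` samples cohort-wide: Fisher
#' exact p, cross-product odds ratio (high vs low/moderate orientation),
#' BH q-value over tested genes, and the significance rule `q < 0.05 &
#' |log2 OR| > 1`. `direction` records which group carries the excess.
#'
#' @param mutations binary sample x gene matrix.
#' @param group logical/0-1 per sample: TRUE = high-expression group.
#' @param min_altered cohort-wide minimum altered-sample count (default 3).
#' @return Data frame of enrichment results.
#' @export
gene_level_enrichment <- function(mutations, group, min_altered = 3L) {
  enrichment_rows(mutations, group, "gene", min_altered)
}

#' Collapse gene-level mutations to pathway level
#'
#' A sample counts as altered in a pathway when at least `min_genes` of the
#' pathway's member genes (restricted to genes present in the matrix) are
#' altered. Sets with no overlapping genes are dropped with a warning.
#'
#' @param mutations binary sample x gene matrix.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param min_genes member-alteration threshold (default 1: any member).
#' @return Binary sample x pathway matrix.
#' @export
pathway_collapse <- function(mutations, sets, min_genes = 1L) {
  kept <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], colnames(mutations))
    if (!length(genes)) {
      warnf("gene set %s has no overlap with the mutation matrix; dropped", nm)
      next
    }
    kept[[nm]] <- as.integer(
      rowSums(mutations[, genes, drop = FALSE]) >= min_genes)
  }
  if (!length(kept)) stopf("no gene set overlaps the mutation matrix")
  out <- do.call(cbind, kept)
  rownames(out) <- rownames(mutations)
  out
}

#' Pathway-level mutation enrichment
#'
#' @param collapsed binary sample x pathway matrix from
#'   [pathway_collapse()].
#' @param group logical/0-1 per sample: TRUE = high-expression group.
#' @param min_altered cohort-wide minimum (default 3).
#' @return Data frame of enrichment results (level = "pathway").
#' @export
pathway_level_enrichment <- function(collapsed, group, min_altered = 3L) {
  enrichment_rows(collapsed, group, "pathway", min_altered)
}

#' Bonferroni-corrected comparison of the most frequently altered genes
#'
#' Takes the union of the top-`k` most frequently altered genes in each
#' group (ties broken by descending frequency, then gene name), computes a
#' Fisher exact p per union gene, and applies the Bonferroni threshold
#' `alpha / u` where `u` is the union size.
#'
#' @param mutations binary sample x gene matrix.
#' @param group logical/0-1 per sample: TRUE = high-expression group.
#' @param k per-group top list size (default 20).
#' @param alpha family-wise error target (default 0.05).
#' @return List with `table` (per-gene frequencies, p, significance),
#'   `union_size`, and `threshold` (= alpha / union_size).
#' @export
bonferroni_topk_comparison <- function(mutations, group, k = 20L,
                                       alpha = 0.05) {
  if (k < 1L) stopf("k must be >= 1")
  group <- as.logical(group)
  if (k > ncol(mutations)) {
    warnf("k = %d exceeds the %d available genes; truncated", k,
          ncol(mutations))
    k <- ncol(mutations)
  }
  top_of <- function(freq) {
    ord <- order(-freq, names(freq))
    names(freq)[ord][seq_len(k)]
  }
  f_high <- colMeans(mutations[group, , drop = FALSE])
  f_low <- colMeans(mutations[!group, , drop = FALSE])
  union_genes <- sort(union(top_of(f_high), top_of(f_low)))
  u <- length(union_genes)
  threshold <- alpha / u
  n1 <- sum(group); n2 <- sum(!group)
  tab <- do.call(rbind, lapply(union_genes, function(g) {
    a <- sum(mutations[group, g]); c_ <- sum(mutations[!group, g])
    fe <- fisher_exact_2x2(a, n1 - a, c_, n2 - c_)
    data.frame(gene = g, freq_high = a / n1, freq_low_moderate = c_ / n2,
               p_value = fe$p_value, significant = fe$p_value < threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, union_size = u, threshold = threshold)
}
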