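# Two-group differential expression with an empirical-Bayes moderated
# t-statistic: per-gene two-sample linear model, variance shrinkage toward
# a common prior estimated by moment-matching on the log residual
# variances, and Benjamini-Hochberg adjustment.

#' Log2 transform of non-negative expression values
#'
#' @param x non-negative numeric matrix or vector (e.g. nRPM).
#' @param pseudocount added before the log (default 1).
#' @return `log2(x + pseudocount)`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (any(x < 0, na.rm = TRUE)) stopf("expression values must be non-negative")
  log2(x + pseudocount)
}

# Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Moment-matching fit of the scaled inverse-chi-square prior for residual
# variances: returns prior df d0 (possibly Inf) and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- var(e) - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    # no excess spread: variances look exchangeable, infinite prior df
    return(list(d0 = Inf, s0_sq = exp(ebar + digamma(df / 2) - log(df / 2))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

#' Empirical-Bayes moderated-t two-group contrast
#'
#' For each gene (row) of a log2 expression matrix, fits the two-group
#' linear model, shrinks the residual variance toward a common prior
#' (estimated from all genes by moment-matching on the log variances), and
#' tests the group difference with a t-statistic on augmented degrees of
#' freedom `d0 + (n - 2)`. P-values are Benjamini-Hochberg adjusted over
#' all tested genes; a gene is called differentially expressed when
#' `adj_p < p_threshold` and `|log2_fc| >= lfc_threshold`.
#'
#' @param log_expr numeric matrix, genes x samples, on the log2 scale.
#' @param group logical or 0/1 vector per sample; `TRUE`/1 is the "high"
#'   group, and `log2_fc` is high minus low/moderate.
#' @param gene_class optional named character vector mapping genes to a
#'   class label (e.g. checkpoint vs non-immune control).
#' @param p_threshold,lfc_threshold DEG call rule (defaults 0.05 and 0.5).
#' @param prior_df,prior_var optional overrides for the variance prior
#'   (`d0`, `s0^2`); by default both are estimated from the data.
#' @return Data frame with `gene`, `log2_fc`, `moderated_t`, `p_value`,
#'   `adj_p`, `is_deg`, `gene_class`; attributes `d0` and `s0_sq`.
#' @export
moderated_t_contrast <- function(log_expr, group, gene_class = NULL,
                                 p_threshold = 0.05, lfc_threshold = 0.5,
                                 prior_df = NULL, prior_var = NULL) {
  log_expr <- as.matrix(log_expr)
  group <- as.logical(group)
  if (length(group) != ncol(log_expr))
    stopf("group length must match the number of samples")
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 < 2L || n2 < 2L) stopf("both groups need at least 2 samples")
  if (nrow(log_expr) < 2L) stopf("need at least 2 genes")

  m1 <- rowMeans(log_expr[, group, drop = FALSE])
  m2 <- rowMeans(log_expr[, !group, drop = FALSE])
  ss1 <- rowSums((log_expr[, group, drop = FALSE] - m1)^2)
  ss2 <- rowSums((log_expr[, !group, drop = FALSE] - m2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df_resid

  zero_var <- s2 <= 0
  if (all(zero_var)) stopf("all genes have zero residual variance")

  prior <- list(d0 = prior_df, s0_sq = prior_var)
  if (is.null(prior$d0) || is.null(prior$s0_sq)) {
    est <- fit_variance_prior(s2[!zero_var], df_resid)
    prior$d0 <- prior$d0 %||% est$d0
    prior$s0_sq <- prior$s0_sq %||% est$s0_sq
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  df_total <- if (is.infinite(d0)) Inf else d0 + df_resid

  lfc <- m1 - m2
  tstat <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = df_total)
  # zero-variance genes with zero shrinkage target would give infinite t
  if (any(zero_var) && s0_sq <= 0) {
    tstat[zero_var] <- NA; p[zero_var] <- NA
    warnf("zero-variance genes flagged (no prior variance to shrink to): %s",
          paste(rownames(log_expr)[zero_var], collapse = ", "))
  }
  adj <- benjamini_hochberg(p)
  genes <- rownames(log_expr) %||% as.character(seq_len(nrow(log_expr)))
  cls <- if (is.null(gene_class)) rep("other", length(genes)) else
    unname(ifelse(is.na(gene_class[genes]), "other", gene_class[genes]))
  out <- data.frame(
    gene = genes, log2_fc = unname(lfc), moderated_t = unname(tstat),
    p_value = unname(p), adj_p = unname(adj),
    is_deg = !is.na(adj) & adj < p_threshold & abs(lfc) >= lfc_threshold,
    gene_class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- df_resid
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_p[(i)] = min_{j >= i} (m * p[(j)] / j)`,
#' capped at 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in (0, 1]; NAs pass through.
#' @return Adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stopf("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Row-wise z-scores of an expression matrix
#'
#' @param log_expr numeric matrix, genes x samples.
#' @return Matrix of `(x - row mean) / row sd`; constant rows are flagged
#'   with a warning and returned as NA.
#' @export
zscore_rows <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  mu <- rowMeans(log_expr)
  sdv <- apply(log_expr, 1, sd)
  flat <- sdv == 0
  if (any(flat)) {
    warnf("constant rows have undefined z-scores: %s",
          paste(rownames(log_expr)[flat], collapse = ", "))
    sdv[flat] <- NA
  }
  (log_expr - mu) / sdv
}

#' Volcano-plot table from a contrast result
#'
#' @param results data frame from [moderated_t_contrast()].
#' @return The input with `neg_log10_adj_p` and `significant` columns
#'   (significant = the DEG call).
#' @export
volcano_table <- function(results) {
  if (!nrow(results)) stopf("empty contrast result")
  results$neg_log10_adj_p <- -log10(results$adj_p)
  results$significant <- results$is_deg
  results
}
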