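# Cohort assembly and association statistics for the three-level
# (low/moderate/high) transcript classification.

#' Merge percentile profiles and clinical covariates into a cohort table
#'
#' Produces one row per sample with `rank_<gene>` and `cat_<gene>` columns
#' for each tracked gene alongside the clinical fields, the substrate for
#' every downstream association, contrast and survival analysis.
#'
#' @param profiles long data frame from [rank_cohort()].
#' @param clinical clinical data frame (see [read_clinical()]).
#' @param genes genes to track; default all genes present in `profiles`.
#' @return Data frame, one row per sample present in both inputs.
#' @export
build_cohort_table <- function(profiles, clinical, genes = NULL) {
  genes <- genes %||% unique(profiles$gene)
  wide <- clinical[clinical$sample_id %in% unique(profiles$sample_id), ,
                   drop = FALSE]
  for (g in genes) {
    sub <- profiles[profiles$gene == g, ]
    idx <- match(wide$sample_id, sub$sample_id)
    wide[[paste0("rank_", g)]] <- sub$rank[idx]
    wide[[paste0("cat_", g)]] <- sub$category[idx]
  }
  wide
}

#' Indicator of high expression for one gene
#'
#' @param table cohort table from [build_cohort_table()].
#' @param gene tracked gene id.
#' @return Integer 0/1 vector: 1 iff the gene's category is `high`
#'   (percentile rank >= 75).
#' @export
binarize_high <- function(table, gene) {
  col <- paste0("cat_", gene)
  if (!col %in% colnames(table)) stopf("gene %s is not tracked", gene)
  as.integer(table[[col]] == "high")
}

#' Per-cancer-type landscape of expression categories
#'
#' For each cancer type with at least `min_samples` samples, the fraction
#' of samples with low, moderate and high expression of `gene`, plus an
#' "All Cancers" row over every sample.
#'
#' @param table cohort table.
#' @param gene tracked gene.
#' @param min_samples minimum per-type sample count (default 11, i.e. more
#'   than 10 representative samples).
#' @return Data frame: `cancer_type`, `n`, `frac_low`, `frac_moderate`,
#'   `frac_high`.
#' @export
landscape_by_type <- function(table, gene, min_samples = 11L) {
  if (!nrow(table)) stopf("empty cohort table")
  if (min_samples < 1L) stopf("min_samples must be >= 1")
  cat_col <- paste0("cat_", gene)
  fracs <- function(rows) {
    tab <- table(factor(rows[[cat_col]], levels = c("low", "moderate", "high")))
    n <- sum(tab)
    data.frame(n = n, frac_low = tab[["low"]] / n,
               frac_moderate = tab[["moderate"]] / n,
               frac_high = tab[["high"]] / n)
  }
  all_row <- cbind(data.frame(cancer_type = "All Cancers"), fracs(table))
  types <- names(which(table(table$cancer_type) >= min_samples))
  per_type <- do.call(rbind, lapply(sort(types), function(ty)
    cbind(data.frame(cancer_type = ty),
          fracs(table[table$cancer_type == ty, , drop = FALSE]))))
  out <- rbind(all_row, per_type)
  rownames(out) <- NULL
  out
}

#' Receptor-high / ligand-low-moderate agonist-candidate profile
#'
#' Flags samples in which the receptor transcript is high (rank >= 75)
#' while the ligand is low-moderate (rank < 75) — the expression profile
#' most amenable to receptor-agonist therapy — and reports the per-type
#' fraction for types with at least `min_samples` samples.
#'
#' @param table cohort table.
#' @param receptor,ligand tracked genes (must differ).
#' @param min_samples per-type minimum (default 20).
#' @return List with `flagged` (logical per sample) and `by_type` (data
#'   frame `cancer_type`, `n`, `n_flagged`, `fraction`).
#' @export
agonist_candidate_profile <- function(table, receptor = "CD40",
                                      ligand = "CD40LG", min_samples = 20L) {
  if (identical(receptor, ligand)) stopf("receptor and ligand must differ")
  r_rank <- table[[paste0("rank_", receptor)]]
  l_rank <- table[[paste0("rank_", ligand)]]
  if (is.null(r_rank) || is.null(l_rank))
    stopf("both %s and %s must be tracked", receptor, ligand)
  flagged <- r_rank >= 75 & l_rank < 75
  types <- names(which(table(table$cancer_type) >= min_samples))
  by_type <- do.call(rbind, lapply(sort(types), function(ty) {
    sel <- table$cancer_type == ty
    data.frame(cancer_type = ty, n = sum(sel), n_flagged = sum(flagged[sel]),
               fraction = mean(flagged[sel]))
  }))
  list(flagged = flagged, by_type = by_type)
}

#' Univariable odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` — identical to the exponentiated
#' single-covariate logistic MLE — with a Wald 95% CI on the log scale and
#' a two-sided Wald p-value. Tables with a zero cell receive the
#' Haldane-Anscombe +0.5 correction to every cell and are flagged.
#'
#' Orientation: `a` = exposed & outcome, `b` = exposed & no outcome,
#' `c` = unexposed & outcome, `d` = unexposed & no outcome.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param variable,condition optional labels carried into the result.
#' @return Data frame row with `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`,
#'   the counts, and a `corrected` flag.
#' @export
univariable_or <- function(a, b, c, d, variable = NA_character_,
                           condition = NA_character_) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stopf("both margins must be positive")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- log_or / se
  data.frame(
    variable = variable, condition = condition, stage = "univariable",
    a = a, b = b, c = c, d = d,
    odds_ratio = exp(log_or),
    ci_lo = exp(log_or - qnorm(0.975) * se),
    ci_hi = exp(log_or + qnorm(0.975) * se),
    p_value = 2 * pnorm(-abs(z)),
    corrected = corrected, stringsAsFactors = FALSE)
}

# 2x2 counts of binary exposure vs binary outcome, NA rows dropped
# (complete-case, mirroring per-variable availability in univariable
# screens).
crosstab_counts <- function(exposure, outcome) {
  keep <- !is.na(exposure) & !is.na(outcome)
  e <- exposure[keep]; o <- outcome[keep]
  c(a = sum(e & o), b = sum(e & !o), c = sum(!e & o), d = sum(!e & !o))
}

#' Build the default candidate-variable list for the association screen
#'
#' Candidates: age >= 61, male sex, MSI-unstable, TMB >= 10 mut/Mb, PD-L1
#' IHC positivity, high expression of every tracked immune gene other than
#' the outcome gene, and indicator variables for each cancer type that has
#' at least 15 samples and/or a higher high-expression fraction than the
#' cohort average.
#'
#' @param table cohort table.
#' @param outcome_gene the gene defining the outcome (excluded from
#'   candidates).
#' @param immune_genes tracked immune genes to offer as candidates.
#' @return Named list of binary (logical/NA) vectors.
#' @export
candidate_variables <- function(table, outcome_gene = "CD40",
                                immune_genes = NULL) {
  out_high <- binarize_high(table, outcome_gene) == 1
  cand <- list()
  overall <- mean(out_high)
  type_tab <- table(table$cancer_type)
  for (ty in sort(names(type_tab))) {
    sel <- table$cancer_type == ty
    if (type_tab[[ty]] >= 15L || mean(out_high[sel]) > overall)
      cand[[paste0("type_", ty)]] <- sel
  }
  cand[["age_ge_61"]] <- table$age_years >= 61
  cand[["sex_male"]] <- table$sex == "male"
  if ("msi" %in% colnames(table))
    cand[["msi_unstable"]] <- ifelse(is.na(table$msi), NA,
                                     table$msi == "unstable")
  if ("tmb_high" %in% colnames(table)) cand[["tmb_high"]] <- table$tmb_high
  if ("pdl1_ihc_positive" %in% colnames(table))
    cand[["pdl1_positive"]] <- table$pdl1_ihc_positive
  immune_genes <- immune_genes %||%
    sub("^cat_", "", grep("^cat_", colnames(table), value = TRUE))
  for (g in setdiff(immune_genes, outcome_gene))
    cand[[paste0("high_", g)]] <- binarize_high(table, g) == 1
  cand
}

#' Univariable association screen
#'
#' One 2x2 odds ratio per candidate variable against high expression of
#' the outcome gene; variables with p <= alpha are selected for the
#' multivariable model. Constant candidates are skipped with a warning.
#'
#' @param table cohort table.
#' @param outcome_gene tracked gene defining the outcome.
#' @param candidates named list of binary vectors; default
#'   [candidate_variables()].
#' @param alpha selection threshold (default 0.05).
#' @return List with `results` (data frame of [univariable_or()] rows) and
#'   `selected` (character vector of variable names).
#' @export
univariable_screen <- function(table, outcome_gene = "CD40",
                               candidates = NULL, alpha = 0.05) {
  candidates <- candidates %||% candidate_variables(table, outcome_gene)
  if (!length(candidates)) stopf("candidate set is empty")
  outcome <- binarize_high(table, outcome_gene) == 1
  rows <- list()
  for (nm in names(candidates)) {
    cc <- crosstab_counts(candidates[[nm]], outcome)
    if (cc[["a"]] + cc[["b"]] == 0 || cc[["c"]] + cc[["d"]] == 0) {
      warnf("candidate %s has no variation; skipped", nm)
      next
    }
    if ((cc[["a"]] + cc[["c"]]) == 0 || (cc[["b"]] + cc[["d"]]) == 0) {
      warnf("outcome margin degenerate for %s; skipped", nm)
      next
    }
    rows[[nm]] <- univariable_or(cc[["a"]], cc[["b"]], cc[["c"]], cc[["d"]],
                                 variable = nm, condition = "TRUE vs FALSE")
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       selected = results$variable[results$p_value <= alpha])
}

#' Tie-aware Spearman correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t-approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stopf("Spearman rho undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Cross-tabulation of two high-expression signatures
#'
#' 2x2 table of `gene_a` high vs a combined signature (high if any of the
#' `signature_genes` is high, by default), with per-row percentages
#' (nearest percent) and a two-sided Fisher exact p-value.
#'
#' @param table cohort table.
#' @param gene_a row gene (e.g. the receptor of interest).
#' @param signature_genes genes combined into the column signature.
#' @param rule `"any"` (default) or `"all"`: how signature genes combine.
#' @return List with `counts` (a, b, c, d), `row_percent` (percent of each
#'   `gene_a` group carrying the signature), and `p_value`.
#' @export
crosstab_signature <- function(table, gene_a = "CD40",
                               signature_genes = c("CD4", "CD8A"),
                               rule = c("any", "all")) {
  rule <- match.arg(rule)
  a_high <- binarize_high(table, gene_a) == 1
  sig <- vapply(signature_genes, function(g) binarize_high(table, g) == 1,
                logical(nrow(table)))
  sig_high <- if (rule == "any") rowSums(sig) > 0 else rowSums(sig) == length(signature_genes)
  cc <- crosstab_counts(a_high, sig_high)
  if ((cc[["a"]] + cc[["b"]]) == 0 || (cc[["c"]] + cc[["d"]]) == 0)
    stopf("empty margin in signature cross-tab")
  fp <- fisher_exact_2x2(cc[["a"]], cc[["b"]], cc[["c"]], cc[["d"]])
  list(counts = cc,
       row_percent = c(
         high = round(100 * cc[["a"]] / (cc[["a"]] + cc[["b"]])),
         low_moderate = round(100 * cc[["c"]] / (cc[["c"]] + cc[["d"]]))),
       p_value = fp$p_value)
}
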