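# End-to-end orchestration: simulate -> normalize -> associate ->
# contrast -> enrich -> survive, with file-based stage outputs so each
# stage is also runnable standalone, and a consolidated JSON report.

#' Pipeline run configuration
#'
#' @param seed master seed; all stage randomness derives from it.
#' @param out_dir output directory for stage files and the report.
#' @param gene_of_interest gene whose high/low-moderate split drives the
#'   grouping analyses (default CD40).
#' @param ligand_gene ligand paired with the gene of interest for the
#'   agonist-candidate profile (default CD40LG).
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param mi_m,mi_burnin multiple-imputation settings.
#' @param screen_alpha univariable selection threshold.
#' @param deg_p,deg_lfc DEG call rule.
#' @param topk top-list size for the Bonferroni mutation comparison.
#' @param survival_covariates extra cohort columns entered alongside the
#'   gene of interest in the Cox models.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("immunorank_run_"),
                       gene_of_interest = "CD40", ligand_gene = "CD40LG",
                       sim = NULL, mi_m = 20L, mi_burnin = 10L,
                       screen_alpha = 0.05, deg_p = 0.05, deg_lfc = 0.5,
                       topk = 20L,
                       survival_covariates = c("age_years", "sex_male")) {
  stopifnot(screen_alpha > 0, screen_alpha < 1, deg_p > 0, deg_p < 1)
  structure(list(seed = seed, out_dir = out_dir,
                 gene_of_interest = gene_of_interest,
                 ligand_gene = ligand_gene,
                 sim = sim %||% sim_config(seed = seed),
                 mi_m = mi_m, mi_burnin = mi_burnin,
                 screen_alpha = screen_alpha, deg_p = deg_p,
                 deg_lfc = deg_lfc, topk = topk,
                 survival_covariates = survival_covariates),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the reference and study cohorts, writes all fixture files,
#' ranks the study cohort against the locked reference model, and runs
#' every analysis stage: landscape, agonist-candidate profile, univariable
#' screen + multiply-imputed multivariable logistic model, rank
#' correlations, moderated-t contrast with z-scores and volcano table,
#' gene/pathway mutation enrichment with the Bonferroni top-k comparison,
#' and the three survival analyses (gene of interest binary and
#' continuous). All stage outputs are written under `config$out_dir` and
#' returned in a single report object.
#'
#' @param config a [run_config()].
#' @return An `analysis_report` list; also written as `report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  goi <- config$gene_of_interest
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ref <- stage("simulate_reference", generate_reference(config$sim))
  study <- stage("simulate_study", generate_study_cohort(config$sim))
  gsets <- stage("simulate_genesets", generate_genesets(config$sim))
  paths <- stage("write_fixtures",
                 write_fixtures(ref, study, gsets, config$out_dir))

  profiles <- stage("normalize", rank_cohort(study$panel, ref$model))
  write_percentiles(profiles, file.path(config$out_dir, "percentiles.tsv"))
  cohort <- stage("cohort_table",
                  build_cohort_table(profiles, study$clinical))
  cohort$sex_male <- cohort$sex == "male"

  landscape <- stage("landscape", landscape_by_type(cohort, goi))
  agonist <- stage("agonist_profile",
                   agonist_candidate_profile(cohort, goi, config$ligand_gene))

  screen <- stage("univariable_screen",
                  univariable_screen(cohort, goi, alpha = config$screen_alpha))
  mi_input <- data.frame(outcome_high = binarize_high(cohort, goi))
  cand <- candidate_variables(cohort, goi)
  for (v in screen$selected) mi_input[[v]] <- as.numeric(cand[[v]])
  multivariable <- if (length(screen$selected)) {
    stage("multivariable_mi", multivariable_logistic_mi(
      mi_input, "outcome_high", screen$selected, m = config$mi_m,
      seed = substream_seed(config$seed, 41L), burnin = config$mi_burnin))
  } else NULL

  correlations <- stage("correlations", {
    others <- setdiff(sub("^rank_", "",
                          grep("^rank_", colnames(cohort), value = TRUE)),
                      goi)
    do.call(rbind, lapply(others, function(g) {
      sp <- spearman_assoc(cohort[[paste0("rank_", goi)]],
                           cohort[[paste0("rank_", g)]])
      data.frame(gene = g, rho = sp$rho, p_value = sp$p_value)
    }))
  })
  tcell <- stage("tcell_crosstab",
                 crosstab_signature(cohort, goi, c("CD4", "CD8A")))

  nrpm_mat <- stage("contrast_input", {
    genes <- unique(profiles$gene)
    wide <- matrix(NA_real_, length(genes), nrow(cohort),
                   dimnames = list(genes, cohort$sample_id))
    idx <- profiles$sample_id %in% cohort$sample_id
    wide[cbind(match(profiles$gene[idx], genes),
               match(profiles$sample_id[idx], cohort$sample_id))] <-
      profiles$nrpm[idx]
    wide
  })
  group_high <- binarize_high(cohort, goi) == 1
  gene_class <- c(setNames(rep("checkpoint", length(config$sim$immune_genes)),
                           config$sim$immune_genes),
                  setNames(rep("non_immune_control",
                               length(config$sim$control_genes)),
                           config$sim$control_genes))
  contrast <- stage("contrast", {
    res <- moderated_t_contrast(log_transform(nrpm_mat), group_high,
                                gene_class = gene_class,
                                p_threshold = config$deg_p,
                                lfc_threshold = config$deg_lfc)
    volcano_table(res)
  })
  zsc <- stage("zscores", zscore_rows(log_transform(nrpm_mat)))

  mut <- study$mutations[cohort$sample_id, , drop = FALSE]
  enrich_gene <- stage("enrich_gene",
                       gene_level_enrichment(mut, group_high))
  collapsed <- stage("pathway_collapse", pathway_collapse(mut, gsets))
  enrich_pw <- stage("enrich_pathway",
                     pathway_level_enrichment(collapsed, group_high))
  topk <- stage("bonferroni_topk",
                bonferroni_topk_comparison(mut, group_high, k = config$topk))

  surv_sets <- stage("survival_cohorts", build_survival_cohorts(cohort))
  surv <- stage("survival_models", {
    lapply(surv_sets[c("os_naive", "os_ici", "pfs_ici")], function(df) {
      if (!nrow(df) || sum(df$event) < 2) return(NULL)
      grp <- df[[paste0("cat_", goi)]] == "high"
      covs <- intersect(config$survival_covariates, colnames(df))
      fit_b <- tryCatch(
        cox_fit(transform(df, goi_high = as.numeric(grp)),
                "time_months", "event", c("goi_high", covs)),
        error = function(e) NULL)
      fit_c <- tryCatch(
        cox_fit(df, "time_months", "event",
                c(paste0("rank_", goi), covs)),
        error = function(e) NULL)
      list(km_high = km_estimate(df$time_months[grp], df$event[grp]),
           km_low_moderate = km_estimate(df$time_months[!grp],
                                         df$event[!grp]),
           logrank = logrank_test(df$time_months, df$event, grp),
           cox_binary = if (!is.null(fit_b)) fit_b$coefficients,
           cox_continuous = if (!is.null(fit_c)) fit_c$coefficients)
    })
  })

  report <- structure(list(
    provenance = list(seed = config$seed,
                      package_version = as.character(packageVersion("immunorank")),
                      gene_of_interest = goi, ligand_gene = config$ligand_gene,
                      n_reference = config$sim$n_reference,
                      n_study = config$sim$n_study),
    landscape = landscape, agonist_profile = agonist$by_type,
    univariable = screen$results, selected = screen$selected,
    multivariable = multivariable, correlations = correlations,
    tcell_crosstab = tcell, contrast = contrast,
    enrichment_gene = enrich_gene, enrichment_pathway = enrich_pw,
    bonferroni_topk = topk, survival = surv,
    qc_failed = attr(profiles, "qc_failed")),
    class = "analysis_report")

  write.table(landscape, file.path(config$out_dir, "landscape.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(contrast, file.path(config$out_dir, "contrast.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(enrich_gene, file.path(config$out_dir, "enrichment_gene.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(enrich_pw, file.path(config$out_dir, "enrichment_pathway.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    strip_unserializable(report),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  report
}

# survfit/coxph handles cannot go to JSON; drop them recursively.
strip_unserializable <- function(x) {
  if (inherits(x, c("coxph", "survfit"))) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_unserializable)
    attributes(x) <- attributes(x)["names"]
  }
  x
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("immunorank analysis report\n")
  cat(sprintf("  gene of interest: %s (seed %s)\n",
              x$provenance$gene_of_interest, x$provenance$seed))
  cat(sprintf("  cohort: %d study / %d reference samples\n",
              x$provenance$n_study, x$provenance$n_reference))
  all_row <- x$landscape[x$landscape$cancer_type == "All Cancers", ]
  cat(sprintf("  high-%s fraction (all cancers): %.1f%%\n",
              x$provenance$gene_of_interest, 100 * all_row$frac_high))
  cat(sprintf("  univariable screen: %d candidates, %d selected\n",
              nrow(x$univariable), length(x$selected)))
  cat(sprintf("  DEGs: %d of %d genes\n", sum(x$contrast$is_deg),
              nrow(x$contrast)))
  cat(sprintf("  significant mutation enrichments: %d gene-level, %d pathway-level\n",
              sum(x$enrichment_gene$significant),
              sum(x$enrichment_pathway$significant)))
  invisible(x)
}

#' Validate a set of pipeline input files for mutual consistency
#'
#' Checks sample-id concordance across the counts, clinical and mutation
#' files, rank/category consistency in a percentile table, and GMT
#' parseability. Always returns a report rather than failing.
#'
#' @param counts,clinical,mutations,percentiles,gmt file paths (any may be
#'   NULL to skip its checks).
#' @return Data frame with columns `check`, `detail` (one row per
#'   violation; zero rows means all checks passed).
#' @export
validate_inputs <- function(counts = NULL, clinical = NULL, mutations = NULL,
                            percentiles = NULL, gmt = NULL) {
  bad <- list()
  note <- function(check, detail)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail)
  panel <- NULL
  if (!is.null(counts)) {
    panel <- tryCatch(read_panel_counts(counts), error = function(e) {
      note("counts_readable", conditionMessage(e)); NULL
    })
  }
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- tryCatch(read_clinical(clinical), error = function(e) {
      note("clinical_readable", conditionMessage(e)); NULL
    })
    if (!is.null(clin) && !is.null(panel)) {
      unknown <- setdiff(clin$sample_id, panel$sample_ids)
      for (s in unknown)
        note("clinical_sample_unknown",
             sprintf("clinical row for unknown sample id %s", s))
    }
  }
  if (!is.null(mutations)) {
    mut <- tryCatch(read_mutations(mutations), error = function(e) {
      note("mutations_readable", conditionMessage(e)); NULL
    })
    if (!is.null(mut) && !is.null(clin)) {
      unknown <- setdiff(rownames(mut), clin$sample_id)
      for (s in unknown)
        note("mutation_sample_unknown",
             sprintf("mutation row for unknown sample id %s", s))
    }
  }
  if (!is.null(percentiles)) {
    pct <- tryCatch(read_percentiles(percentiles), error = function(e) {
      note("percentiles_readable", conditionMessage(e)); NULL
    })
    if (!is.null(pct)) {
      out_of_range <- pct$rank < 0 | pct$rank > 100
      if (any(out_of_range))
        note("rank_out_of_range",
             sprintf("%d rank values outside [0, 100]", sum(out_of_range)))
      inconsistent <- !is.na(pct$rank) & !out_of_range &
        pct$category != as.character(categorize(pmin(pmax(pct$rank, 0), 100)))
      if (any(inconsistent))
        note("category_inconsistent",
             sprintf("%d rows where category does not match rank",
                     sum(inconsistent)))
    }
  }
  if (!is.null(gmt)) {
    tryCatch(read_gmt(gmt), error = function(e)
      note("gmt_readable", conditionMessage(e)))
  }
  if (!length(bad))
    return(data.frame(check = character(0), detail = character(0)))
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}
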