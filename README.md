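# immunorank

Reference-cohort percentile ranking and association analysis for targeted
immune RNA panels.

## The problem

Targeted immune-transcript panels (tens of genes, FFPE tumor tissue,
batch-wise sequencing with no-template controls) are used to profile
checkpoint and co-stimulatory receptors — CD40, PD-1/PD-L1/PD-L2, CTLA-4,
LAG-3, ICOS, 4-1BB, CD27, CD28, OX40, GITR — across pan-cancer cohorts, to
ask which tumors might respond to agonist or checkpoint-blockade therapy.
Raw counts are not comparable across runs or samples, and absolute
abundances are not comparable across genes, so the field works in
*percentile ranks against a locked reference cohort*: a tumor's CD40 level
is reported as "the 83rd percentile of a fixed pan-cancer reference
population", and classified **high** (rank ≥ 75), **moderate** (25–74) or
**low** (< 25).

`immunorank` implements that measurement chain and every downstream
analysis a profiling study of this design needs, for analysts who have
panel counts + clinical + mutation data (or want a fully synthetic but
statistically faithful stand-in):

* **Normalization** — per-batch NTC background subtraction, RPM
  conversion, and housekeeping median-ratio scaling to nRPM:
  `nRPM_g = RPM_g / median_h(RPM_h / profile_h)` over the 10 HK genes `h`.
* **Ranking** — mid-rank percentiles against per-gene reference
  distributions, three-level classification.
* **Association** — per-type landscapes, receptor-high/ligand-low
  agonist-candidate profiling, univariable odds-ratio screens (cross-product
  OR = exponentiated logistic MLE, Wald CI), multivariable logistic
  regression with chained-equation multiple imputation and Rubin's-rules
  pooling, tie-aware Spearman correlations, Fisher cross-tabs.
* **Differential expression** — empirical-Bayes moderated-t contrast
  (high vs low/moderate) with Benjamini–Hochberg adjustment and the
  adjusted-p < 0.05, |log2 FC| ≥ 0.5 call rule; z-score and volcano tables.
* **Mutation enrichment** — gene- and hallmark-pathway-level Fisher exact
  tests (q < 0.05 and |log2 OR| > 1), plus the Bonferroni-corrected
  comparison of each group's top-20 most frequently altered genes.
* **Survival** — Kaplan–Meier, log-rank, and Cox proportional-hazards
  models with the gene of interest binary or as continuous rank.
* **Synthetic cohorts** — a seeded generator (latent immune-infiltration
  factor, cancer-type shifts, MAR missingness, factor-linked mutations,
  proportional-hazards survival) that makes the entire pipeline testable
  without patient-level data.

See `vignettes/immunorank-methods.Rmd` for the statistical details and
every default's rationale.

## Worked example

```r
library(immunorank)

cfg      <- sim_config(seed = 7)           # 735 reference + 514 study samples
ref      <- generate_reference(cfg)        # counts + locked reference model
study    <- generate_study_cohort(cfg)     # counts, clinical, mutations
profiles <- rank_cohort(study$panel, ref$model)
head(profiles[profiles$gene == "CD40", ], 3)
#>   sample_id gene      nrpm      rank category
#> 1    PT0001 CD40  920.6417  6.394558      low
#> 2    PT0002 CD40 1732.0806 17.959184      low
#> 3    PT0003 CD40 1039.2763  8.843537      low

cohort <- build_cohort_table(profiles, study$clinical)
ls <- landscape_by_type(cohort, "CD40")
head(ls[order(-ls$frac_high), ], 3)
#>        cancer_type  n frac_low frac_moderate frac_high
#> 6  liver_bile_duct 16   0.0625         0.312     0.625
#> 10      pancreatic 51   0.0196         0.431     0.549
#> 9          ovarian 46   0.0870         0.500     0.413
```

Liver/bile-duct, pancreatic and ovarian tumors have the largest high-CD40
fractions — the ordering the generator's cancer-type shifts encode. The
univariable screen and rank correlation on the same cohort:

```r
scr <- univariable_screen(cohort, "CD40")
head(scr$results[order(scr$results$p_value),
                 c("variable", "odds_ratio", "ci_lo", "ci_hi", "p_value")], 3)
#>         variable odds_ratio ci_lo ci_hi  p_value
#> 31 high_TNFRSF18       4.44  2.84  6.94 6.20e-11
#> 26     high_ICOS       4.08  2.62  6.34 4.20e-10
#> 29     high_CD28       3.63  2.34  5.63 9.04e-09

sp <- spearman_assoc(cohort$rank_CD40, cohort$rank_CD28)
sprintf("Spearman rho = %.2f (p = %.2g)", sp$rho, sp$p_value)
#> "Spearman rho = 0.41 (p = 9.6e-23)"
```

High CD40 travels with the other co-stimulatory receptors (odds ratios of
3.4–4.4 here), the co-expression signature the latent-factor generator is
built to produce. The same functions accept real data read with
`read_panel_counts()`, `read_clinical()`, `read_mutations()`,
`read_reference_model()` and `read_gmt()`.

Published contingency tables for a 514-sample pan-cancer CD40 cohort ship
with the package as worked inputs:

```r
r <- univariable_or(23, 32, 91, 368)   # pancreatic cancer vs high CD40
sprintf("OR %.1f (95%% CI %.1f-%.1f)", r$odds_ratio, r$ci_lo, r$ci_hi)
#> "OR 2.9 (95% CI 1.6-5.2)"
```

`run_pipeline(run_config(seed = 1))` chains every stage (simulate →
normalize → associate → contrast → enrich → survive) into one
seed-deterministic run with per-stage TSV outputs and a consolidated JSON
report; `inst/scripts/immunorank.R` exposes the same stages as a thin
command-line wrapper.

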