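# Synthetic pan-cancer immune cohort generator.
#
# Emulates the data a targeted immune RNA panel produces: Poisson read
# counts whose log-means combine a per-gene baseline, a latent
# immune-infiltration factor (shared by checkpoint/co-stimulatory genes,
# zero for housekeeping and control genes), and cancer-type-specific log2
# shifts; per-batch no-template-control background; clinical covariates
# with missing-at-random MSI/TMB; binary somatic mutations logistically
# linked to the immune factor; and proportional-hazards survival times.

panel_gene_defaults <- function() {
  immune <- c(CD40 = 10.0, PDCD1 = 8.5, CD274 = 9.0, PDCD1LG2 = 8.8,
              CTLA4 = 8.2, LAG3 = 8.8, ICOS = 8.4, TNFRSF9 = 8.0,
              CD27 = 9.2, CD28 = 9.0, TNFRSF4 = 8.3, TNFRSF18 = 8.1)
  ligand_tcell <- c(CD40LG = 6.0, CD4 = 10.5, CD8A = 9.5)
  hk <- c(ACTB = 15.5, B2M = 15.0, GAPDH = 15.2, GUSB = 12.0, HPRT1 = 11.5,
          PGK1 = 13.0, POLR2A = 12.2, PPIA = 14.0, RPLP0 = 14.5, TBP = 11.0)
  controls <- c(MKI67 = 11.0, MYC = 11.5, ERBB2 = 10.5, EGFR = 10.8,
                EPCAM = 12.5, KRT19 = 12.8, MUC1 = 11.8, CEACAM5 = 10.0,
                AFP = 7.0, TERT = 8.0)
  list(
    base_log2 = c(immune, ligand_tcell, hk, controls),
    immune_genes = names(immune),
    hk_genes = names(hk),
    control_genes = names(controls),
    loadings = c(CD40 = 1.0, PDCD1 = 0.9, CD274 = 0.8, PDCD1LG2 = 0.8,
                 CTLA4 = 0.9, LAG3 = 0.9, ICOS = 0.9, TNFRSF9 = 0.8,
                 CD27 = 0.9, CD28 = 1.0, TNFRSF4 = 0.8, TNFRSF18 = 0.7,
                 CD40LG = 0.6, CD4 = 1.0, CD8A = 1.0))
}

cancer_type_defaults <- function() {
  # Composition mirrors a ~514-sample pan-cancer referral cohort dominated
  # by colorectal, pancreatic and breast cancer, with a long tail of rare
  # histologies (31 types).
  n <- c(colorectal = 140, pancreatic = 55, breast = 49, ovarian = 43,
         stomach = 25, sarcoma = 24, uterine = 24, lung = 20,
         liver_bile_duct = 19, neuroendocrine = 15, head_and_neck = 13,
         unknown_primary = 13, melanoma = 9, kidney = 8, prostate = 7,
         bladder = 7, esophageal = 6, brain = 6, thyroid = 5, cervical = 5,
         appendiceal = 4, salivary = 4, mesothelioma = 4, adrenal = 3,
         testicular = 3, anal = 2, thymic = 2, vulvar = 2, small_bowel = 2,
         penile = 2, gallbladder = 3)
  n / sum(n)
}

type_shift_defaults <- function() {
  # CD40 runs high in liver/bile-duct, pancreatic and ovarian tumors and
  # low in colorectal and head-and-neck disease.
  data.frame(
    type = c("liver_bile_duct", "pancreatic", "ovarian", "neuroendocrine",
             "colorectal", "head_and_neck"),
    gene = "CD40",
    log2_shift = c(1.1, 1.1, 1.0, 0.6, -0.7, -1.0),
    stringsAsFactors = FALSE)
}

mutation_defaults <- function() {
  genes <- c("TP53", "KRAS", "APC", "CDKN2A", "SMAD4", "ARID1A", "PIK3CA",
             "BRAF", "PTEN", "EGFR", "SMAD2", "CTNNB1", "FBXW7", "ATM",
             "BRCA2", "KMT2D", "NOTCH1", "RB1", "NF1", "ERBB2", "GNAS",
             "STK11", "CDH1", "TGFBR2", "BUB1B", "PIK3R1", "MTOR", "AKT1",
             "SMARCA4", "RNF43", "CCND1")
  base <- setNames(rep(-3.2, length(genes)), genes)
  base[c("TP53", "KRAS", "APC", "CDKN2A", "SMAD4", "ARID1A", "PIK3CA")] <-
    c(0.0, -1.2, -1.5, -1.9, -2.1, -2.0, -2.0)
  base[c("BRAF", "PTEN", "EGFR", "ATM", "KMT2D")] <- -2.6
  slope <- setNames(rep(0, length(genes)), genes)
  # APC (and other WNT/TGF-beta axis genes) anti-correlate with immune
  # infiltration; CCND1 tracks with it.
  slope[c("APC", "TGFBR2", "SMAD2", "SMAD4", "BUB1B", "MTOR")] <-
    c(-1.0, -0.8, -0.6, -0.4, -0.6, -0.5)
  slope["CCND1"] <- 0.8
  list(genes = genes, base_logodds = base, factor_slope = slope)
}

#' Configuration for the synthetic cohort generator
#'
#' Returns the full parameter set controlling cohort generation. Defaults
#' emulate the study conditions the package targets: a 735-sample
#' pan-cancer reference cohort, a 514-sample study cohort over 31 cancer
#' types, a latent immune-infiltration factor inducing positive
#' co-expression among the 12 immune genes plus CD40LG/CD4/CD8A,
#' cancer-type-specific CD40 shifts, missing-at-random MSI/TMB, mutations
#' logistically tied to the immune factor (APC negatively), and
#' proportional-hazards survival with random censoring.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   substream from it.
#' @param n_reference,n_study cohort sizes.
#' @param cancer_type_weights named probabilities summing to 1.
#' @param genes named numeric of per-gene baseline log2 abundance.
#' @param hk_genes,immune_genes,control_genes gene-id partitions.
#' @param gene_loadings named numeric loadings on the latent immune factor
#'   (genes absent from the vector load 0; housekeeping genes must load 0).
#' @param immune_factor_sd standard deviation of the latent factor.
#' @param noise_sd per-sample-per-gene log2 biological noise SD; with the
#'   default loadings this yields rank correlations of roughly 0.3-0.45
#'   among immune genes, the regime targeted by the generator.
#' @param type_shifts data frame (`type`, `gene`, `log2_shift`).
#' @param depth_range length-2 numeric, uniform range of per-sample total
#'   reads.
#' @param background_rate mean NTC reads per gene (Poisson).
#' @param n_batches sequencing batches, each with one NTC.
#' @param missing_rate_msi,missing_rate_tmb marginal missingness
#'   probabilities; realized missingness is a function of cancer type only
#'   (missing at random).
#' @param msi_rate,tmb_shape,tmb_rate,pdl1_rate clinical marginals: MSI-high
#'   Bernoulli rate; gamma(shape, rate) mutations/Mb for TMB (dichotomized
#'   at >= 10); PD-L1 IHC CPS >= 1 rate.
#' @param mutation_genes,mutation_base_logodds,mutation_factor_slope binary
#'   mutation model: logit P(altered) = base + slope * (factor / factor sd).
#' @param hazard_coefficients named log-hazard-ratios; recognized names are
#'   `immune_factor` (per SD of the latent factor) and `age` (per year,
#'   centered at 61).
#' @param baseline_hazard events per month for OS from advanced disease.
#' @param censor_rate probability a subject receives a random censoring
#'   time (uniform on (0, max follow-up)); 0 means no censoring.
#' @param max_followup_months administrative cut-off.
#' @param ici_fraction fraction of the survival-evaluable cohort exposed to
#'   immune checkpoint inhibitors.
#' @param survival_evaluable_rate fraction of study samples with usable
#'   survival data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_reference = 735L,
                       n_study = 514L,
                       cancer_type_weights = cancer_type_defaults(),
                       genes = panel_gene_defaults()$base_log2,
                       hk_genes = panel_gene_defaults()$hk_genes,
                       immune_genes = panel_gene_defaults()$immune_genes,
                       control_genes = panel_gene_defaults()$control_genes,
                       gene_loadings = panel_gene_defaults()$loadings,
                       immune_factor_sd = 0.8,
                       noise_sd = 1.0,
                       type_shifts = type_shift_defaults(),
                       depth_range = c(2e5, 1e6),
                       background_rate = 5,
                       n_batches = 8L,
                       missing_rate_msi = 0.066,
                       missing_rate_tmb = 0.125,
                       msi_rate = 0.03,
                       tmb_shape = 2, tmb_rate = 0.45,
                       pdl1_rate = 0.30,
                       mutation_genes = mutation_defaults()$genes,
                       mutation_base_logodds = mutation_defaults()$base_logodds,
                       mutation_factor_slope = mutation_defaults()$factor_slope,
                       hazard_coefficients = c(immune_factor = -0.25,
                                               age = 0.02),
                       baseline_hazard = log(2) / 40,
                       censor_rate = 0.35,
                       max_followup_months = 84,
                       ici_fraction = 217 / 489,
                       survival_evaluable_rate = 489 / 514) {
  if (abs(sum(cancer_type_weights) - 1) > 1e-9)
    stopf("cancer_type_weights must sum to 1")
  if (!length(cancer_type_weights)) stopf("cancer_type_weights is empty")
  if (any(depth_range <= 0) || depth_range[1] > depth_range[2])
    stopf("depth_range must be positive and ordered")
  if (!all(hk_genes %in% names(genes)))
    stopf("hk_genes must appear in the gene list")
  loading_full <- setNames(rep(0, length(genes)), names(genes))
  loading_full[names(gene_loadings)] <- gene_loadings
  if (any(loading_full[hk_genes] != 0))
    stopf("housekeeping genes must have zero loading on the immune factor")
  if (immune_factor_sd < 0) stopf("immune_factor_sd must be non-negative")
  stopifnot(missing_rate_msi >= 0, missing_rate_msi <= 1,
            missing_rate_tmb >= 0, missing_rate_tmb <= 1,
            censor_rate >= 0, censor_rate <= 1)
  structure(list(
    seed = seed, n_reference = as.integer(n_reference),
    n_study = as.integer(n_study),
    cancer_type_weights = cancer_type_weights,
    genes = genes, hk_genes = hk_genes, immune_genes = immune_genes,
    control_genes = control_genes, gene_loadings = loading_full,
    immune_factor_sd = immune_factor_sd, noise_sd = noise_sd,
    type_shifts = type_shifts,
    depth_range = depth_range, background_rate = background_rate,
    n_batches = as.integer(n_batches),
    missing_rate_msi = missing_rate_msi, missing_rate_tmb = missing_rate_tmb,
    msi_rate = msi_rate, tmb_shape = tmb_shape, tmb_rate = tmb_rate,
    pdl1_rate = pdl1_rate,
    mutation_genes = mutation_genes,
    mutation_base_logodds = mutation_base_logodds,
    mutation_factor_slope = mutation_factor_slope,
    hazard_coefficients = hazard_coefficients,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    max_followup_months = max_followup_months,
    ici_fraction = ici_fraction,
    survival_evaluable_rate = survival_evaluable_rate),
    class = "sim_config")
}

# Shift matrix (types x genes) from the long type_shifts frame.
shift_lookup <- function(config, types) {
  shifts <- matrix(0, length(types), length(config$genes),
                   dimnames = list(types, names(config$genes)))
  ts <- config$type_shifts
  if (!is.null(ts) && nrow(ts)) {
    for (i in seq_len(nrow(ts))) {
      if (ts$type[i] %in% types && ts$gene[i] %in% colnames(shifts))
        shifts[ts$type[i], ts$gene[i]] <- ts$log2_shift[i]
    }
  }
  shifts
}

# Draw raw counts for n samples with latent factors `fac` and cancer types
# `types`. Counts are Poisson around depth-scaled relative abundances plus
# Poisson background; one NTC per batch.
draw_counts <- function(config, n, fac, types, prefix) {
  genes <- names(config$genes)
  shifts <- shift_lookup(config, unique(types))
  log2_mu <- matrix(rep(config$genes, each = n), n, length(genes),
                    dimnames = list(NULL, genes))
  log2_mu <- log2_mu + outer(fac, config$gene_loadings[genes])
  log2_mu <- log2_mu + shifts[types, , drop = FALSE]
  if (config$noise_sd > 0)
    log2_mu <- log2_mu + matrix(rnorm(n * length(genes), 0, config$noise_sd),
                                n, length(genes))
  w <- 2^log2_mu
  p <- w / rowSums(w)
  depth <- runif(n, config$depth_range[1], config$depth_range[2])
  signal <- matrix(rpois(n * length(genes), lambda = p * depth),
                   n, length(genes))
  bg <- matrix(rpois(n * length(genes), lambda = config$background_rate),
               n, length(genes))
  counts <- signal + bg
  dimnames(counts) <- list(sprintf("%s%04d", prefix, seq_len(n)), genes)
  batch <- setNames(
    sprintf("B%02d", 1L + (seq_len(n) - 1L) %% config$n_batches),
    rownames(counts))
  ntc <- matrix(rpois(config$n_batches * length(genes),
                      lambda = config$background_rate),
                config$n_batches, length(genes),
                dimnames = list(sprintf("B%02d", seq_len(config$n_batches)),
                                genes))
  panel_counts(counts, batch, ntc)
}

#' Generate the reference cohort and its locked reference model
#'
#' @param config a [sim_config()].
#' @return List with `panel` (a [panel_counts()]), `model` (a
#'   [reference_model()] built from it), and `immune_factor` (the latent
#'   factor values, for diagnostics).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reference < 10L) stopf("n_reference must be at least 10")
  with_rng(substream_seed(config$seed, 11L), {
    n <- config$n_reference
    types <- sample(names(config$cancer_type_weights), n, replace = TRUE,
                    prob = config$cancer_type_weights)
    fac <- rnorm(n, 0, config$immune_factor_sd)
    panel <- draw_counts(config, n, fac, types, "REF")
    list(panel = panel,
         model = build_reference_model(panel, config$hk_genes),
         immune_factor = setNames(fac, panel$sample_ids))
  })
}

#' Generate the study cohort: counts, clinical table, mutation matrix
#'
#' Clinical covariates: cancer type from the configured weights; age
#' ~ Normal(61, 12) truncated to 18-95; sex (60% female); MSI and TMB with
#' missing-at-random gaps driven by cancer type; PD-L1 IHC positivity
#' correlated with the immune factor. Survival: overall survival from
#' advanced disease for all evaluable patients, and OS/PFS from therapy
#' start for the ICI-exposed subset, all exponential proportional-hazards
#' with the configured coefficients and random censoring.
#'
#' @param config a [sim_config()].
#' @return List with `panel`, `clinical` (data frame), `mutations` (binary
#'   sample x gene matrix), and `immune_factor`.
#' @export
generate_study_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(substream_seed(config$seed, 23L), {
    n <- config$n_study
    types <- sample(names(config$cancer_type_weights), n, replace = TRUE,
                    prob = config$cancer_type_weights)
    fac <- rnorm(n, 0, config$immune_factor_sd)
    panel <- draw_counts(config, n, fac, types, "PT")
    ids <- panel$sample_ids
    fs <- if (config$immune_factor_sd > 0) fac / config$immune_factor_sd else fac

    age <- pmin(pmax(round(rnorm(n, 61, 12)), 18), 95)
    sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.60, 0.40))
    msi <- ifelse(rbinom(n, 1, config$msi_rate) == 1, "unstable", "stable")
    tmb <- rgamma(n, shape = config$tmb_shape, rate = config$tmb_rate)
    pdl1 <- rbinom(n, 1, plogis(qlogis(config$pdl1_rate) + 0.4 * fs)) == 1

    # MAR missingness: probability depends only on the (always observed)
    # cancer type, scaled to hit the configured marginal rate.
    mar_mult <- ifelse(types %in% c("colorectal", "breast"), 1.5, 1)
    mar_mult <- mar_mult / mean(mar_mult)
    miss_msi <- rbinom(n, 1, pmin(config$missing_rate_msi * mar_mult, 1)) == 1
    miss_tmb <- rbinom(n, 1, pmin(config$missing_rate_tmb * mar_mult, 1)) == 1
    msi[miss_msi] <- NA
    tmb[miss_tmb] <- NA

    mut <- sapply(config$mutation_genes, function(g) {
      pr <- plogis(config$mutation_base_logodds[[g]] +
                     (config$mutation_factor_slope[[g]] %||% 0) * fs)
      rbinom(n, 1, pr)
    })
    dimnames(mut) <- list(ids, config$mutation_genes)

    evaluable <- rbinom(n, 1, config$survival_evaluable_rate) == 1
    ici <- evaluable & rbinom(n, 1, config$ici_fraction) == 1
    lp <- (config$hazard_coefficients[["immune_factor"]] %||% 0) * fs +
      (config$hazard_coefficients[["age"]] %||% 0) * (age - 61)

    draw_surv <- function(base_rate) {
      t_event <- rexp(n, rate = config$baseline_hazard * base_rate * exp(lp))
      censored <- rbinom(n, 1, config$censor_rate) == 1
      t_cens <- ifelse(censored,
                       runif(n, 0, config$max_followup_months),
                       config$max_followup_months)
      time <- pmax(pmin(t_event, t_cens), 1e-3)
      event <- as.integer(t_event <= t_cens)
      list(time = time, event = event)
    }
    os_adv <- draw_surv(1)
    os_ici <- draw_surv(2)    # post-ICI clocks run faster: shorter horizon
    pfs_ici <- draw_surv(6)

    clinical <- data.frame(
      sample_id = ids, cancer_type = types, age_years = age, sex = sex,
      msi = msi, tmb_mut_per_mb = tmb, tmb_high = tmb >= 10,
      pdl1_ihc_positive = pdl1,
      survival_evaluable = evaluable, ici_treated = ici,
      os_adv_months = ifelse(evaluable & !ici, os_adv$time, NA),
      os_adv_event = ifelse(evaluable & !ici, os_adv$event, NA),
      os_ici_months = ifelse(ici, os_ici$time, NA),
      os_ici_event = ifelse(ici, os_ici$event, NA),
      pfs_ici_months = ifelse(ici, pfs_ici$time, NA),
      pfs_ici_event = ifelse(ici, pmax(pfs_ici$event, os_ici$event *
                               (os_ici$time <= pfs_ici$time)), NA),
      stringsAsFactors = FALSE)

    list(panel = panel, clinical = clinical, mutations = mut,
         immune_factor = setNames(fac, ids))
  })
}

#' Generate a hallmark-like gene-set collection
#'
#' Builds 50 named gene sets over the configured mutation genes: four
#' curated pathway sets (WNT/beta-catenin, TGF-beta signaling, mitotic
#' spindle, PI3K/AKT/mTOR) plus seeded random sets of 3-8 genes, with every
#' mutation gene covered by at least one set.
#'
#' @param config a [sim_config()].
#' @param n_sets number of sets (default 50).
#' @return Named list of character vectors (a `GeneSetCollection`).
#' @export
generate_genesets <- function(config, n_sets = 50L) {
  genes <- config$mutation_genes
  curated <- list(
    HM_WNT_BETA_CATENIN = intersect(c("APC", "CTNNB1", "RNF43", "FBXW7",
                                      "GNAS"), genes),
    HM_TGF_BETA_SIGNALING = intersect(c("SMAD4", "SMAD2", "TGFBR2", "APC"),
                                      genes),
    HM_MITOTIC_SPINDLE = intersect(c("BUB1B", "SMARCA4", "KMT2D", "NF1"),
                                   genes),
    HM_PI3K_AKT_MTOR = intersect(c("PIK3CA", "PIK3R1", "AKT1", "MTOR",
                                   "PTEN", "STK11"), genes))
  with_rng(substream_seed(config$seed, 37L), {
    sets <- curated
    i <- 0L
    while (length(sets) < n_sets) {
      i <- i + 1L
      sets[[sprintf("HM_SET_%02d", i)]] <-
        sort(sample(genes, sample(3:8, 1)))
    }
    # guarantee coverage: fold any uncovered gene into the last set
    uncovered <- setdiff(genes, unique(unlist(sets)))
    if (length(uncovered))
      sets[[length(sets)]] <- sort(union(sets[[length(sets)]], uncovered))
    sets
  })
}

#' Write a generated cohort to plain-text fixture files
#'
#' Emits `counts.tsv` (sample, batch, then gene columns; NTC rows named
#' `NTC_<batch>`), `clinical.csv`, `mutations.tsv` (long sample/gene/0-1),
#' `hallmark_like.gmt`, and `reference_model.json`. All files round-trip
#' losslessly through the package readers.
#'
#' @param reference output of [generate_reference()].
#' @param study output of [generate_study_cohort()].
#' @param genesets output of [generate_genesets()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixtures <- function(reference, study, genesets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             reference_counts = file.path(dir, "reference_counts.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             mutations = file.path(dir, "mutations.tsv"),
             gmt = file.path(dir, "hallmark_like.gmt"),
             model = file.path(dir, "reference_model.json"))
  write_panel_counts(study$panel, paths[["counts"]])
  write_panel_counts(reference$panel, paths[["reference_counts"]])
  write.csv(study$clinical, paths[["clinical"]], row.names = FALSE)
  mut_long <- data.frame(
    sample_id = rep(rownames(study$mutations), ncol(study$mutations)),
    gene = rep(colnames(study$mutations), each = nrow(study$mutations)),
    altered = as.integer(study$mutations))
  write.table(mut_long, paths[["mutations"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write_gmt(genesets, paths[["gmt"]])
  write_reference_model(reference$model, paths[["model"]])
  invisible(paths)
}
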