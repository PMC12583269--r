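test_that("generation is deterministic and counts are non-negative integers", {
  cfg <- tiny_config(seed = 42)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(a$panel$counts, b$panel$counts)
  expect_identical(a$model$reference_nrpm, b$model$reference_nrpm)
  expect_true(all(a$panel$counts >= 0))
  expect_true(all(a$panel$counts == round(a$panel$counts)))
  s1 <- generate_study_cohort(cfg)
  s2 <- generate_study_cohort(cfg)
  expect_identical(s1$panel$counts, s2$panel$counts)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$mutations, s2$mutations)
})

test_that("fixture files are hash-identical across reruns and round-trip", {
  cfg <- tiny_config(seed = 8)
  dirs <- c(withr::local_tempdir(), withr::local_tempdir())
  for (d in dirs) {
    ref <- generate_reference(cfg)
    study <- generate_study_cohort(cfg)
    write_fixtures(ref, study, generate_genesets(cfg), d)
  }
  for (f in list.files(dirs[[1]])) {
    expect_identical(unname(tools::md5sum(file.path(dirs[[1]], f))),
                     unname(tools::md5sum(file.path(dirs[[2]], f))),
                     label = f)
  }
  # lossless round-trip through the package readers
  d <- dirs[[1]]
  study <- generate_study_cohort(cfg)
  panel <- read_panel_counts(file.path(d, "counts.tsv"))
  expect_equal(panel$counts, study$panel$counts)
  expect_identical(panel$batch, study$panel$batch)
  expect_equal(panel$ntc, study$panel$ntc)
  mut <- read_mutations(file.path(d, "mutations.tsv"))
  expect_equal(mut[rownames(study$mutations), colnames(study$mutations)],
               study$mutations)
  clin <- read_clinical(file.path(d, "clinical.csv"))
  expect_equal(clin$sample_id, study$clinical$sample_id)
  expect_equal(clin$age_years, study$clinical$age_years)
})

test_that("GMT serialization preserves set membership", {
  sets <- list(SetA = c("TP53", "KRAS"), SetB = c("APC", "SMAD4", "PTEN"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[1], "\t")[[1]][1], "SetA")
  expect_identical(read_gmt(path), sets)
  writeLines("Bad\tonly-description", path)
  expect_error(read_gmt(path), "malformed")
})

test_that("latent immune factor induces the expected co-expression", {
  cfg <- sim_config(seed = 2, immune_factor_sd = 0.8)
  ref <- generate_reference(cfg)
  le <- log2(ref$panel$counts + 1)
  expect_gt(cor(le[, "CD40"], le[, "CD28"], method = "spearman"), 0.3)
  # housekeeping genes do not load on the factor
  expect_lt(abs(cor(ref$immune_factor, le[, "ACTB"], method = "spearman")),
            0.2)
})

test_that("APC mutations anti-correlate with the immune factor", {
  cfg <- sim_config(seed = 3, n_study = 5000)
  study <- generate_study_cohort(cfg)
  q <- quantile(study$immune_factor, c(0.25, 0.75))
  f_top <- mean(study$mutations[study$immune_factor >= q[2], "APC"])
  f_bot <- mean(study$mutations[study$immune_factor <= q[1], "APC"])
  expect_lt(f_top, f_bot)
  # CCND1 has the opposite slope
  expect_gt(mean(study$mutations[study$immune_factor >= q[2], "CCND1"]),
            mean(study$mutations[study$immune_factor <= q[1], "CCND1"]))
})

test_that("MSI/TMB missingness follows the configured rates", {
  cfg <- tiny_config(seed = 4, missing_rate_msi = 0, missing_rate_tmb = 0)
  study <- generate_study_cohort(cfg)
  expect_false(anyNA(study$clinical$msi))
  expect_false(anyNA(study$clinical$tmb_high))
  cfg2 <- sim_config(seed = 4, n_study = 2000, missing_rate_msi = 0.2)
  study2 <- generate_study_cohort(cfg2)
  expect_equal(mean(is.na(study2$clinical$msi)), 0.2, tolerance = 0.15)
})

test_that("with no type shifts, study percentile ranks are uniform over the reference", {
  no_shift <- data.frame(type = character(0), gene = character(0),
                         log2_shift = numeric(0))
  cfg <- sim_config(seed = 6, type_shifts = no_shift)
  ref <- generate_reference(cfg)
  study <- generate_study_cohort(cfg)
  prof <- rank_cohort(study$panel, ref$model)
  ranks <- prof$rank[prof$gene == "CD40"]
  ks <- suppressWarnings(stats::ks.test(ranks / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a +2 log2 CD40 shift raises that type's high fraction above average", {
  shifts <- data.frame(type = "pancreatic", gene = "CD40", log2_shift = 2)
  cfg <- sim_config(
    seed = 9, n_reference = 200, n_study = 200,
    cancer_type_weights = c(pancreatic = 0.5, colorectal = 0.5),
    type_shifts = shifts)
  ref <- generate_reference(cfg)
  study <- generate_study_cohort(cfg)
  ct <- build_cohort_table(rank_cohort(study$panel, ref$model),
                           study$clinical)
  high <- binarize_high(ct, "CD40")
  expect_gt(mean(high[ct$cancer_type == "pancreatic"]), mean(high))
})

test_that("null hazard with no censoring gives uniform log-rank p-values", {
  ps <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 100 + i, n_study = 150,
                      hazard_coefficients = c(immune_factor = 0, age = 0),
                      censor_rate = 0, survival_evaluable_rate = 1,
                      ici_fraction = 0)
    study <- generate_study_cohort(cfg)
    cl <- study$clinical
    logrank_test(cl$os_adv_months, cl$os_adv_event,
                 cl$sex == "male")$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("generated gene sets cover all mutation genes and collapse cleanly", {
  cfg <- sim_config(seed = 12)
  sets <- generate_genesets(cfg)
  expect_length(sets, 50L)
  expect_setequal(unique(unlist(sets)), cfg$mutation_genes)
  study <- generate_study_cohort(cfg)
  collapsed <- pathway_collapse(study$mutations, sets)
  expect_true(all(colSums(collapsed) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cancer_type_weights = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(sim_config(depth_range = c(-1, 10)), "depth_range")
  expect_error(sim_config(gene_loadings = c(ACTB = 1)), "zero loading")
})
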