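test_that("univariable odds ratios reproduce worked 2x2 examples", {
  r <- univariable_or(23, 32, 91, 368)
  expect_equal(round(r$odds_ratio, 1), 2.9)
  r2 <- univariable_or(2, 13, 105, 360)
  expect_equal(round(r2$odds_ratio, 2), 0.53)
  r3 <- univariable_or(5, 5, 5, 5)
  expect_equal(r3$odds_ratio, 1.0)
  expect_true(r3$ci_lo < 1 && r3$ci_hi > 1)
})

test_that("cross-product OR equals the logistic MLE with matching Wald inference", {
  set.seed(31)
  for (rep in 1:100) {
    cells <- rpois(4, 25) + 1   # non-degenerate
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    r <- univariable_or(a, b, c_, d)
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    x <- c(rep(1, a + b), rep(0, c_ + d))
    fit <- glm(y ~ x, family = binomial())
    sm <- summary(fit)$coefficients
    expect_equal(r$odds_ratio, unname(exp(coef(fit)["x"])), tolerance = 1e-6)
    expect_equal(r$p_value, unname(sm["x", "Pr(>|z|)"]), tolerance = 1e-3)
  }
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  r <- univariable_or(50, 0, 0, 50)
  expect_true(r$corrected)
  expect_true(is.finite(r$odds_ratio) && r$odds_ratio > 1)
  expect_error(univariable_or(0, 0, 5, 5), "margins")
})

test_that("consistent published univariable rows reproduce the printed column", {
  tab <- published_univariable_counts()
  for (i in which(tab$consistent)) {
    r <- univariable_or(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
    digits <- if (tab$printed_or[i] < 1) 2 else 1
    expect_equal(round(r$odds_ratio, digits), tab$printed_or[i],
                 label = tab$variable[i])
  }
})

test_that("the univariable screen selects the strong cancer-type signals, not age or sex", {
  ct <- published_cohort_fixture()
  scr <- univariable_screen(ct, "CD40")
  expect_true(all(c("type_pancreatic", "type_ovarian",
                    "type_liver_bile_duct") %in% scr$selected))
  expect_false("age_ge_61" %in% scr$selected)
  expect_false("sex_male" %in% scr$selected)
  expect_false("msi_unstable" %in% scr$selected)
  # reported counts agree with the printed table they were built from
  panc <- scr$results[scr$results$variable == "type_pancreatic", ]
  expect_equal(c(panc$a, panc$b, panc$c, panc$d), c(23, 32, 91, 368))
})

test_that("under the null the screen's per-variable false-selection rate is ~alpha", {
  set.seed(77)
  hits <- vapply(1:1000, function(i) {
    x <- rbinom(200, 1, 0.4) == 1
    y <- rbinom(200, 1, 0.3) == 1
    a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
    univariable_or(a, b, c_, d)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("constant candidates are skipped with a warning", {
  ct <- published_cohort_fixture()
  cand <- list(flat = rep(TRUE, nrow(ct)),
               real = ct$cancer_type == "pancreatic")
  expect_warning(scr <- univariable_screen(ct, "CD40", candidates = cand),
                 "no variation")
  expect_equal(scr$results$variable, "real")
})

test_that("Spearman correlation is tie-aware and matches the midrank oracle", {
  x <- 1:10
  expect_equal(spearman_assoc(x, x^3)$rho, 1.0)
  expect_equal(spearman_assoc(x, rev(x))$rho, -1.0)
  set.seed(41)
  xt <- sample(rep(1:5, each = 4)); yt <- xt + rnorm(20)
  sp <- spearman_assoc(xt, yt)
  # independent oracle: Pearson on mid-ranks
  mr <- function(v) rank(v, ties.method = "average")
  expect_equal(sp$rho, cor(mr(xt), mr(yt)), tolerance = 1e-12)
  expect_equal(sp$rho, cor(xt, yt, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
})

test_that("signature cross-tab reproduces the published CD40 vs CD4/8 row percent", {
  cc <- published_cd4cd8_crosstab()
  # reconstruct a cohort with exactly those margins (CD8A never high)
  n <- sum(cc)
  ct <- data.frame(
    rank_CD40 = c(rep(85, cc["a"] + cc["b"]), rep(50, cc["c"] + cc["d"])),
    rank_CD4 = c(rep(90, cc["a"]), rep(10, cc["b"]),
                 rep(90, cc["c"]), rep(10, cc["d"])),
    rank_CD8A = rep(10, n))
  for (g in c("CD40", "CD4", "CD8A"))
    ct[[paste0("cat_", g)]] <- categorize(ct[[paste0("rank_", g)]])
  res <- crosstab_signature(ct, "CD40", c("CD4", "CD8A"))
  expect_equal(unname(res$counts), unname(cc))
  expect_equal(unname(res$row_percent["high"]), 52)
  expect_equal(unname(res$row_percent["low_moderate"]), 23)
  expect_lt(res$p_value, 0.001)
})

test_that("symmetric cross-tab gives Fisher p of 1", {
  ct <- data.frame(rank_A = c(rep(85, 20), rep(50, 20)),
                   rank_B = rep(c(85, 50), 20))
  ct$cat_A <- categorize(ct$rank_A); ct$cat_B <- categorize(ct$rank_B)
  res <- crosstab_signature(ct, "A", "B")
  expect_equal(res$p_value, 1.0)
})

test_that("landscape fractions sum to one and match group-by counting", {
  cfg <- tiny_config(seed = 14)
  ref <- generate_reference(cfg)
  study <- generate_study_cohort(cfg)
  ct <- build_cohort_table(rank_cohort(study$panel, ref$model),
                           study$clinical)
  ls <- landscape_by_type(ct, "CD40", min_samples = 5)
  expect_equal(ls$frac_low + ls$frac_moderate + ls$frac_high,
               rep(1, nrow(ls)), tolerance = 1e-12)
  for (i in seq_len(nrow(ls))) {
    rows <- if (ls$cancer_type[i] == "All Cancers") ct else
      ct[ct$cancer_type == ls$cancer_type[i], ]
    expect_equal(ls$frac_high[i], mean(rows$cat_CD40 == "high"))
    expect_equal(ls$n[i], nrow(rows))
  }
  # All-Cancers high fraction is the count-weighted mean over all types
  by_type <- tapply(ct$cat_CD40 == "high", ct$cancer_type, mean)
  wts <- table(ct$cancer_type)[names(by_type)]
  expect_equal(ls$frac_high[ls$cancer_type == "All Cancers"],
               sum(by_type * wts) / sum(wts))
  # min_samples above cohort size leaves only the All-Cancers row
  ls2 <- landscape_by_type(ct, "CD40", min_samples = nrow(ct) + 1)
  expect_equal(ls2$cancer_type, "All Cancers")
})

test_that("agonist-candidate profile applies the receptor-high/ligand-low rule", {
  ct <- data.frame(
    cancer_type = rep("ovarian", 4),
    rank_CD40 = c(80, 74.9, 80, 60),
    rank_CD40LG = c(50, 50, 80, 50))
  ct$cat_CD40 <- categorize(ct$rank_CD40)
  ct$cat_CD40LG <- categorize(ct$rank_CD40LG)
  prof <- agonist_candidate_profile(ct, min_samples = 1)
  expect_identical(prof$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(agonist_candidate_profile(ct, receptor = "CD40",
                                         ligand = "CD40"), "differ")
})
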