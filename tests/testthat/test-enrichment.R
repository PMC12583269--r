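test_that("Fisher exact p matches enumeration and the stats oracle", {
  sym <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(sym$p_value, 1.0)
  expect_equal(sym$odds_ratio, 1.0)
  set.seed(51)
  for (rep in 1:60) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    fe <- fisher_exact_2x2(a, b, c_, d)
    expect_equal(fe$p_value, fisher_oracle(a, b, c_, d), tolerance = 1e-10)
    expect_equal(fe$p_value,
                 fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("zero cells and zero margins are handled as documented", {
  fe <- fisher_exact_2x2(10, 0, 0, 10)
  expect_true(fe$corrected && is.finite(fe$odds_ratio) && fe$odds_ratio > 1)
  expect_equal(fe$p_value, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)
  zm <- fisher_exact_2x2(0, 0, 5, 5)
  expect_equal(zm$p_value, 1)
  expect_false(zm$or_defined)
})

test_that("a strong APC-style depletion in the high group is detected with direction", {
  set.seed(52)
  n_high <- 114; n_low <- 400
  group <- c(rep(TRUE, n_high), rep(FALSE, n_low))
  mut <- cbind(
    APC = c(rbinom(n_high, 1, 0.05), rbinom(n_low, 1, 0.21)),
    TP53 = rbinom(n_high + n_low, 1, 0.5),
    KRAS = rbinom(n_high + n_low, 1, 0.25),
    NEVER = rep(0L, n_high + n_low))
  rownames(mut) <- sprintf("S%03d", seq_len(nrow(mut)))
  res <- gene_level_enrichment(mut, group)
  expect_false("NEVER" %in% res$feature)      # filtered: 0 altered samples
  apc <- res[res$feature == "APC", ]
  expect_true(apc$significant)
  expect_equal(apc$direction, "low_moderate")
  expect_lt(apc$log2_or, -1)
})

test_that("permuted labels keep the significant fraction near zero", {
  set.seed(53)
  n <- 200
  mut <- sapply(1:10, function(i) rbinom(n, 1, 0.2))
  colnames(mut) <- sprintf("G%02d", 1:10)
  rownames(mut) <- sprintf("S%03d", 1:n)
  frac <- vapply(1:200, function(i) {
    grp <- sample(c(rep(TRUE, 50), rep(FALSE, 150)))
    mean(gene_level_enrichment(mut, grp)$significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("pathway collapse equals the per-sample set-intersection oracle", {
  set.seed(54)
  mut <- matrix(rbinom(60, 1, 0.3), 10, 6,
                dimnames = list(sprintf("S%02d", 1:10), LETTERS[1:6]))
  sets <- list(P1 = c("A", "B"), P2 = c("C", "D", "E", "Z"), P3 = "F")
  collapsed <- pathway_collapse(mut, sets)
  for (s in rownames(mut)) {
    for (p in names(sets)) {
      altered_genes <- colnames(mut)[mut[s, ] == 1]
      expect_equal(collapsed[s, p],
                   as.integer(length(intersect(sets[[p]], altered_genes)) >= 1),
                   label = paste(s, p))
    }
  }
  # a single altered member suffices; an empty row collapses to all zero
  mut2 <- mut; mut2["S01", ] <- 0
  expect_true(all(pathway_collapse(mut2, sets)["S01", ] == 0))
  expect_warning(pathway_collapse(mut, c(sets, list(P4 = "ZZZ"))),
                 "no overlap")
})

test_that("pathway enrichment flags a spiked set and q = p for a single set", {
  set.seed(55)
  n_high <- 100; n_low <- 300
  group <- c(rep(TRUE, n_high), rep(FALSE, n_low))
  mut <- cbind(SMAD4 = c(rbinom(n_high, 1, 0.03), rbinom(n_low, 1, 0.25)),
               TGFBR2 = c(rbinom(n_high, 1, 0.03), rbinom(n_low, 1, 0.2)),
               TP53 = rbinom(n_high + n_low, 1, 0.5),
               KRAS = rbinom(n_high + n_low, 1, 0.25))
  rownames(mut) <- sprintf("S%03d", seq_len(nrow(mut)))
  sets <- list(TGFB = c("SMAD4", "TGFBR2"), OTHER = c("TP53", "KRAS"))
  collapsed <- pathway_collapse(mut, sets)
  res <- pathway_level_enrichment(collapsed, group)
  tg <- res[res$feature == "TGFB", ]
  expect_true(tg$significant)
  expect_equal(tg$direction, "low_moderate")
  single <- pathway_level_enrichment(collapsed[, "TGFB", drop = FALSE], group)
  expect_equal(single$q_value, single$p_value)
})

test_that("null pathway enrichment stays quiet", {
  set.seed(56)
  n <- 400
  collapsed <- sapply(1:50, function(i) rbinom(n, 1, 0.3))
  colnames(collapsed) <- sprintf("P%02d", 1:50)
  grp <- c(rep(TRUE, 100), rep(FALSE, 300))
  res <- pathway_level_enrichment(collapsed, grp)
  expect_lte(mean(res$significant), 0.05)
})

test_that("the Bonferroni top-k comparison sizes its threshold by the union", {
  set.seed(57)
  n <- 100
  mut <- sapply(1:30, function(i) rbinom(n, 1, 0.3 - i / 200))
  colnames(mut) <- sprintf("G%02d", 1:30)
  rownames(mut) <- sprintf("S%03d", 1:n)
  grp <- c(rep(TRUE, 30), rep(FALSE, 70))
  cmp <- bonferroni_topk_comparison(mut, grp, k = 20)
  expect_equal(cmp$threshold, 0.05 / cmp$union_size)
  expect_equal(cmp$union_size, nrow(cmp$table))

  # k = 1 with a dominant shared top gene: union of one, threshold 0.05
  mut1 <- cbind(TOP = rep(1L, n), RARE = rbinom(n, 1, 0.05))
  rownames(mut1) <- rownames(mut)
  cmp1 <- bonferroni_topk_comparison(mut1, grp, k = 1)
  expect_equal(cmp1$union_size, 1L)
  expect_equal(cmp1$threshold, 0.05)
  expect_equal(cmp1$table$gene, "TOP")

  # deterministic lexicographic tie-break at the cut: BBB and CCC tie for
  # second place in both groups, so BBB wins by name
  mutt <- cbind(AAA = rep(1L, n), BBB = rep(c(0L, 1L), 50),
                CCC = rep(c(0L, 1L), 50))
  rownames(mutt) <- rownames(mut)
  cmpt <- bonferroni_topk_comparison(mutt, grp, k = 2)
  expect_equal(sort(cmpt$table$gene), c("AAA", "BBB"))

  expect_warning(bonferroni_topk_comparison(mut1, grp, k = 5), "truncated")
})

test_that("q-values are monotone in p and the significant set shrinks with min_altered", {
  set.seed(58)
  n <- 300
  grp <- c(rep(TRUE, 80), rep(FALSE, 220))
  mut <- sapply(1:20, function(i)
    rbinom(n, 1, ifelse(i <= 5, 0.1 + 0.2 * grp, 0.15)))
  colnames(mut) <- sprintf("G%02d", 1:20)
  rownames(mut) <- sprintf("S%03d", 1:n)
  res <- gene_level_enrichment(mut, grp, min_altered = 3)
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  res_strict <- gene_level_enrichment(mut, grp, min_altered = 40)
  expect_lte(sum(res_strict$significant), sum(res$significant))
  expect_true(all(res$direction == ifelse(res$log2_or > 0, "high",
                                          "low_moderate")))
})
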