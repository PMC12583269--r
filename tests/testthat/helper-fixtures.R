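# Shared fixtures and independent oracles, built in code at test time.

# A small simulation configuration for fast smoke/property tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_reference = 120L, n_study = 150L, ...)
}

# Hand-built 13-gene panel (3 targets + 10 HK genes), one sample, one batch,
# with round numbers so the nRPM chain can be verified by hand.
worked_panel <- function() {
  genes <- c("A", "B", "C", paste0("HK", sprintf("%02d", 1:10)))
  counts <- matrix(c(110, 60, 30, rep(100, 10)), nrow = 1,
                   dimnames = list("S1", genes))
  ntc <- matrix(c(10, 10, 30, rep(0, 10)), nrow = 1,
                dimnames = list("B1", genes))
  panel_counts(counts, c(S1 = "B1"), ntc)
}

# Reference model whose HK profile is exactly half the worked sample's HK
# RPM, so the Normalization Ratio is exactly 2.
worked_model <- function() {
  hk <- paste0("HK", sprintf("%02d", 1:10))
  hk_rpm <- 100 * 1e6 / 1150          # each HK gene's RPM in the sample
  ref <- lapply(setNames(c("A", "B", "C", hk), c("A", "B", "C", hk)),
                function(g) c(1, 2))  # placeholder distributions
  reference_model(hk, setNames(rep(hk_rpm / 2, 10), hk), ref)
}

# Counting-definition oracle for mid-rank percentile ranks.
rank_oracle <- function(v, ref) {
  100 * (sum(ref < v) + 0.5 * sum(ref == v)) / length(ref)
}

# Brute-force Benjamini-Hochberg: adj_(i) = min over tail of m*p_(j)/j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Exhaustive two-sided Fisher p via choose()-based enumeration over all
# tables with the observed margins (independent of dhyper).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  tab_prob <- function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  probs <- vapply(lo:hi, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Cohort table reproducing the printed per-variable 2x2 margins of the
# published 514-sample cohort: 114 CD40-high samples, with cancer types,
# age, sex, MSI and TMB assigned to match each printed cross-tab.
published_cohort_fixture <- function() {
  n_high <- 114L; n_low <- 400L
  df <- data.frame(
    sample_id = sprintf("S%03d", 1:(n_high + n_low)),
    rank_CD40 = c(rep(85, n_high), rep(50, n_low)),
    stringsAsFactors = FALSE)
  df$cat_CD40 <- categorize(df$rank_CD40)

  assign_types <- function(counts, total) {
    # counts: named vector of per-type sample numbers for this CD40 stratum
    out <- rep("colorectal", total)
    i <- 1L
    for (ty in names(counts)) {
      if (counts[[ty]] > 0) out[i:(i + counts[[ty]] - 1L)] <- ty
      i <- i + counts[[ty]]
    }
    out
  }
  high_types <- c(liver_bile_duct = 8, pancreatic = 23, ovarian = 17,
                  neuroendocrine = 5, sarcoma = 6, stomach = 6,
                  unknown_primary = 3)
  low_types <- c(liver_bile_duct = 11, pancreatic = 32, ovarian = 26,
                 neuroendocrine = 10, sarcoma = 18, stomach = 19,
                 unknown_primary = 10)
  df$cancer_type <- c(assign_types(high_types, n_high),
                      assign_types(low_types, n_low))

  fill <- function(n_true, n_false, n_na, total) {
    stopifnot(n_true + n_false + n_na == total)
    c(rep(TRUE, n_true), rep(FALSE, n_false), rep(NA, n_na))
  }
  df$age_years <- ifelse(c(fill(63, 51, 0, n_high)[1:n_high],
                           fill(193, 207, 0, n_low)[1:n_low]), 70, 50)
  df$sex <- ifelse(c(fill(39, 75, 0, n_high)[1:n_high],
                     fill(165, 235, 0, n_low)[1:n_low]), "male", "female")
  msi_flag <- c(fill(2, 105, 7, n_high), fill(13, 360, 27, n_low))
  df$msi <- ifelse(is.na(msi_flag), NA,
                   ifelse(msi_flag, "unstable", "stable"))
  df$tmb_high <- c(fill(2, 90, 22, n_high), fill(31, 327, 42, n_low))
  df
}
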