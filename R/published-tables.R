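# Contingency tables transcribed from the published 514-sample pan-cancer
# CD40 profiling cohort that this package's workflow mirrors. They serve as
# worked inputs: recomputing the univariable statistics from these printed
# counts reproduces the published odds-ratio columns, which is the
# package's desk-scale validation (the underlying patient-level data are
# not publicly deposited).

#' Printed univariable 2x2 counts for the CD40-high association screen
#'
#' Each row is a published 2x2 table of a candidate variable against high
#' CD40 expression (rank >= 75) in a 514-sample pan-cancer cohort:
#' `a` = variable present & CD40-high, `b` = present & not high,
#' `c` = absent & CD40-high, `d` = absent & not high. `printed_or` is the
#' odds ratio printed alongside (1-2 significant decimals).
#' `consistent` marks rows whose printed counts and odds ratio agree under
#' the cross-product definition; the remaining rows carry internal
#' transcription inconsistencies in the source table and are kept for
#' completeness only.
#'
#' @return Data frame with columns `variable`, `a`, `b`, `c`, `d`,
#'   `printed_or`, `consistent`.
#' @export
published_univariable_counts <- function() {
  df <- read.csv(text = "variable,a,b,c,d,printed_or,consistent
liver_bile_duct,8,11,106,389,2.7,TRUE
pancreatic,23,32,91,368,2.9,TRUE
ovarian,17,26,97,374,2.5,TRUE
neuroendocrine,5,10,109,390,1.3,FALSE
sarcoma,6,18,106,384,1.2,TRUE
stomach,6,19,108,381,1.1,TRUE
unknown_primary,3,10,111,390,1.1,TRUE
age_ge_61,63,193,51,207,1.3,TRUE
sex_male,39,165,75,235,0.74,TRUE
msi_unstable,2,13,105,360,0.53,TRUE
tmb_high,2,31,90,327,0.31,FALSE
pdl1_positive,31,125,46,312,1.6,FALSE
high_PDCD1,44,49,70,351,4.5,TRUE
high_CD274,30,37,84,363,3.5,TRUE
high_PDCD1LG2,38,62,76,338,2.8,FALSE
high_CTLA4,33,54,81,346,2.6,TRUE
high_LAG3,47,69,67,331,3.4,TRUE
high_ICOS,30,40,84,360,3.2,TRUE
high_TNFRSF9,35,42,42,395,3.8,FALSE
high_CD27,42,56,72,344,3.6,TRUE
high_CD28,43,59,71,341,3.5,TRUE
high_TNFRSF4,45,77,69,323,2.7,TRUE
high_TNFRSF18,39,60,75,340,2.9,TRUE
", stringsAsFactors = FALSE)
  df
}

#' Printed CD40 vs CD4/CD8-signature cross-tabulation
#'
#' 2x2 counts of high CD40 expression against the combined CD4/8
#' signature (high CD4 or high CD8) in the same published cohort:
#' 59 of 114 CD40-high and 91 of 400 CD40-low/moderate samples carried the
#' signature.
#'
#' @return Named integer vector `a`, `b`, `c`, `d` (orientation as in
#'   [univariable_or()]).
#' @export
published_cd4cd8_crosstab <- function() {
  c(a = 59L, b = 55L, c = 91L, d = 309L)
}
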