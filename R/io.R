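# Readers and writers for the pipeline's plain-text interchange formats.

#' Write / read panel counts as TSV
#'
#' Layout: one row per sample plus one `NTC_<batch>` row per batch; columns
#' `sample_id`, `batch`, then one column per gene.
#'
#' @param panel a [panel_counts()] object.
#' @param path file path.
#' @return `write_panel_counts` invisibly returns `path`;
#'   `read_panel_counts` returns a [panel_counts()].
#' @export
write_panel_counts <- function(panel, path) {
  stopifnot(inherits(panel, "panel_counts"))
  samp <- data.frame(sample_id = panel$sample_ids,
                     batch = unname(panel$batch[panel$sample_ids]),
                     panel$counts, check.names = FALSE)
  ntc <- data.frame(sample_id = paste0("NTC_", rownames(panel$ntc)),
                    batch = rownames(panel$ntc),
                    panel$ntc, check.names = FALSE)
  write.table(rbind(samp, ntc), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_counts
#' @export
read_panel_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_ntc <- startsWith(df$sample_id, "NTC_")
  genes <- setdiff(colnames(df), c("sample_id", "batch"))
  counts <- as.matrix(df[!is_ntc, genes, drop = FALSE])
  rownames(counts) <- df$sample_id[!is_ntc]
  ntc <- as.matrix(df[is_ntc, genes, drop = FALSE])
  rownames(ntc) <- df$batch[is_ntc]
  panel_counts(counts, setNames(df$batch[!is_ntc], df$sample_id[!is_ntc]),
               ntc)
}

#' Write / read a reference model as JSON
#'
#' Numbers are serialized at full precision so the locked model round-trips
#' bit-identically.
#'
#' @param model a [reference_model()].
#' @param path file path.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  jsonlite::write_json(
    list(hk_genes = model$hk_genes,
         hk_rpm_profile = as.list(model$hk_rpm_profile),
         reference_nrpm = model$reference_nrpm,
         reference_size = model$reference_size),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_model(hk_genes = x$hk_genes,
                  hk_rpm_profile = unlist(x$hk_rpm_profile),
                  reference_nrpm = as.list(x$reference_nrpm))
}

#' Read a clinical table
#' @param path CSV path with the column dictionary produced by
#'   [generate_study_cohort()] / [write_fixtures()].
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "cancer_type", "age_years", "sex")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stopf("clinical table lacks columns: %s", paste(missing, collapse = ", "))
  df
}

#' Read a long-format binary mutation table into a sample x gene matrix
#' @param path TSV with columns `sample_id`, `gene`, `altered` (0/1).
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(df$altered %in% c(0L, 1L)))
    stopf("mutation entries must be 0/1")
  samples <- unique(df$sample_id)
  genes <- unique(df$gene)
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(df$sample_id, samples), match(df$gene, genes))] <-
    as.integer(df$altered)
  m
}

#' Read / write gene sets in GMT format
#'
#' One set per line: `SetName<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stopf("malformed GMT line (need name, description, >=1 gene): %s",
            substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a percentile profile table
#'
#' @param profiles long data frame from [rank_cohort()].
#' @param path TSV path.
#' @export
write_percentiles <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_percentiles
#' @export
read_percentiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = c("low", "moderate", "high"))
  df
}
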