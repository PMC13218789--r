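#' Write a diplotype report
#'
#' Emits the pipeline's per-sample CSV report: sample ID, the star call of
#' each haplotype, copy number, the rendered diplotype string (e.g.
#' `"*1/*4"`, `"*1x2/*1"`, `"*5/*4"`), the activity score (or
#' `"indeterminate"`), the metabolizer phenotype, the phase posterior and
#' any flags. The header is always written; one data row per sample.
#'
#' @param calls a `diplotype_calls` data frame as produced by
#'   [run_pipeline()] (columns `sample_id`, `hap1`, `hap2`, `cnv`,
#'   `diplotype`, `activity_score`, `phenotype`, `phase_posterior`,
#'   `flags`).
#' @param path output file path.
#' @export
write_report <- function(calls, path) {
  cols <- report_columns()
  missing_cols <- setdiff(cols, names(calls))
  if (length(missing_cols) > 0L)
    pgx_validation_error(sprintf("report is missing column(s): %s",
                                 paste(missing_cols, collapse = ", ")))
  header <- paste(cols, collapse = ",")
  if (nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(NULL))
  }
  body <- do.call(paste, c(lapply(calls[cols], as.character), sep = ","))
  writeLines(c(header, body), path)
  invisible(NULL)
}

#' Read a diplotype report
#'
#' Inverse of [write_report()]; all columns are returned as character except
#' `cnv` (integer).
#'
#' @param path report file path.
#' @return A data frame with the report columns.
#' @export
read_report <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) pgx_parse_error("report file is empty")
  fields <- strsplit(lines, ",", fixed = TRUE)
  cols <- fields[[1L]]
  if (!identical(cols, report_columns()))
    pgx_format_error("unexpected report header")
  n <- length(lines) - 1L
  out <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(j) {
      vapply(fields[-1L], function(f) if (j <= length(f)) f[[j]] else "", character(1))
    }), cols),
    stringsAsFactors = FALSE, optional = TRUE)
  if (n == 0L) out <- out[0, , drop = FALSE]
  out$cnv <- as.integer(out$cnv)
  out
}

report_columns <- function() {
  c("sample_id", "hap1", "hap2", "cnv", "diplotype",
    "activity_score", "phenotype", "phase_posterior", "flags")
}

# Fixed-format numbers keep reports byte-stable across runs.
format_as <- function(x) {
  if (is.na(x)) return("indeterminate")
  s <- sub("0+$", "", sprintf("%.4f", x))
  if (endsWith(s, ".")) s <- paste0(s, "0")
  s
}

format_posterior <- function(x) {
  if (is.na(x)) "NA" else sprintf("%.6f", x)
}
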