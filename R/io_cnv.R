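#' Read a copy-number table
#'
#' Two columns — sample ID and integer gene copy number — separated by a
#' comma or a tab (auto-detected per file). A header row is optional and is
#' recognized by a non-integer second field. Samples absent from the table
#' are assumed to carry two gene copies.
#'
#' @param path file path.
#' @param delimiter field delimiter; `NULL` auto-detects.
#' @return A data frame with columns `sample_id` (character) and `copies`
#'   (integer, >= 0).
#' @export
read_cnv_table <- function(path, delimiter = NULL) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) return(data.frame(sample_id = character(0), copies = integer(0)))
  delimiter <- delimiter %||% detect_delimiter(lines[[1L]])
  fields <- lapply(strsplit(lines, delimiter, fixed = TRUE), trimws)
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    pgx_parse_error(sprintf("row %d: expected two fields (sample ID, copy number)", bad[[1L]]))
  # optional header: recognized by a non-numeric second field ("CNV");
  # numeric-but-not-integer values stay data rows so they are rejected below
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][[2L]]))))
    fields <- fields[-1L]
  sample_id <- vapply(fields, `[[`, character(1), 1L)
  copies_chr <- vapply(fields, `[[`, character(1), 2L)
  ok <- grepl("^[-+]?[0-9]+$", copies_chr)
  if (any(!ok))
    pgx_validation_error(sprintf(
      "sample %s: copy number '%s' is not an integer",
      sample_id[!ok][[1L]], copies_chr[!ok][[1L]]))
  copies <- as.integer(copies_chr)
  if (any(copies < 0))
    pgx_validation_error(sprintf(
      "sample %s: copy number must be >= 0, got %d",
      sample_id[copies < 0][[1L]], copies[copies < 0][[1L]]))
  if (anyDuplicated(sample_id))
    pgx_validation_error(sprintf(
      "duplicate sample ID(s) in CNV table: %s",
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  data.frame(sample_id = sample_id, copies = copies, stringsAsFactors = FALSE)
}

#' Write a copy-number table
#'
#' Inverse of [read_cnv_table()]; writes a `ID,CNV` header.
#'
#' @param cnv data frame with columns `sample_id`, `copies`.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
write_cnv_table <- function(cnv, path, delimiter = ",") {
  writeLines(c(paste("ID", "CNV", sep = delimiter),
               paste(cnv$sample_id, cnv$copies, sep = delimiter)), path)
  invisible(NULL)
}

# Per-sample copies for a vector of sample ids; absent samples default to 2.
cnv_for_samples <- function(sample_ids, cnv = NULL) {
  copies <- rep(2L, length(sample_ids))
  if (!is.null(cnv) && nrow(cnv) > 0L) {
    idx <- match(sample_ids, cnv$sample_id)
    copies[!is.na(idx)] <- cnv$copies[idx[!is.na(idx)]]
  }
  names(copies) <- sample_ids
  copies
}
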