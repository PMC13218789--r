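#' Read a genotype table
#'
#' Parses a CSV/TSV genotype table: a header row with a sample-ID column
#' followed by one column per panel variant, then one row per sample. Each
#' cell encodes an unordered allele pair, `"C/T"` by default, or a missing
#' token (`"./."` or an empty cell by default). Allele pairs are
#' canonicalized to sorted order on load so that file order cannot leak a
#' spurious phase signal.
#'
#' @param path file path (or connection) to read.
#' @param delimiter field delimiter; `NULL` (default) auto-detects comma
#'   vs tab from the header line.
#' @param genotype_sep separator between the two alleles within a cell.
#' @param missing_tokens cell values treated as a missing call.
#' @return A list with components `panel` (a [variant_panel] whose
#'   `alleles_observed` are the alleles seen in the file) and `records`
#'   (a list of [genotype_record] objects, in file order).
#' @export
read_genotype_table <- function(path, delimiter = NULL, genotype_sep = "/",
                                missing_tokens = c("./.", "")) {
  lines <- read_text_lines(path)
  if (length(lines) < 1L) pgx_parse_error("genotype table is empty")
  delimiter <- delimiter %||% detect_delimiter(lines[[1L]])
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (length(header) < 2L)
    pgx_parse_error("genotype header must contain a sample-ID column and at least one variant column")
  variant_ids <- header[-1L]
  ncol_exp <- length(header)

  records <- vector("list", length(lines) - 1L)
  seen_ids <- character(0)
  obs <- rep(list(character(0)), length(variant_ids))
  for (i in seq_along(records)) {
    row_no <- i + 1L  # file line number, header is line 1
    f <- trimws(fields[[i + 1L]])
    # trailing empty fields are dropped by strsplit; restore them so that an
    # empty last cell can act as a missing token
    if (length(f) < ncol_exp && endsWith(lines[[i + 1L]], delimiter))
      f <- c(f, rep("", ncol_exp - length(f)))
    if (length(f) != ncol_exp)
      pgx_parse_error(sprintf(
        "row %d: expected %d fields, found %d", row_no, ncol_exp, length(f)))
    sample_id <- f[[1L]]
    if (!nzchar(sample_id))
      pgx_parse_error(sprintf("row %d: empty sample ID", row_no))
    if (sample_id %in% seen_ids)
      pgx_validation_error(sprintf("row %d: duplicate sample ID '%s'", row_no, sample_id))
    seen_ids <- c(seen_ids, sample_id)
    calls <- vector("list", length(variant_ids))
    for (j in seq_along(variant_ids)) {
      cell <- f[[j + 1L]]
      if (cell %in% missing_tokens) {
        calls[[j]] <- NA
        next
      }
      alleles <- strsplit(cell, genotype_sep, fixed = TRUE)[[1L]]
      if (length(alleles) != 2L || any(!nzchar(alleles)))
        pgx_parse_error(sprintf(
          "row %d: cell '%s' at variant %s is not an allele pair ('A%sB') or missing token",
          row_no, cell, variant_ids[[j]], genotype_sep))
      calls[[j]] <- sort_radix(alleles)
      obs[[j]] <- c(obs[[j]], alleles)
    }
    records[[i]] <- genotype_record(sample_id, calls)
  }
  panel <- variant_panel(variant_ids, lapply(obs, unique))
  list(panel = panel, records = records)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; emits the same dialect.
#'
#' @param panel a [variant_panel].
#' @param records list of [genotype_record] objects.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @param genotype_sep within-cell allele separator.
#' @param missing_token token written for a missing call.
#' @export
write_genotype_table <- function(panel, records, path, delimiter = ",",
                                 genotype_sep = "/", missing_token = "./.") {
  header <- paste(c("ID", panel$variant_ids), collapse = delimiter)
  rows <- vapply(records, function(r) {
    cells <- vapply(r$calls, function(x) {
      if (is_missing_call(x)) missing_token else paste(x, collapse = genotype_sep)
    }, character(1))
    paste(c(r$sample_id, cells), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(NULL)
}

read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
}

detect_delimiter <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}
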