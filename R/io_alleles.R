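#' Star-allele definition table
#'
#' Maps star-allele names to their defining haplotype vector over a variant
#' panel, a function category and an activity value. Rows whose haplotype
#' vectors are identical form an *ambiguity group*: the panel cannot
#' distinguish those stars, and matches against any member report all of
#' them.
#'
#' @param star character vector of unique star-allele names (e.g. `"*4"`).
#' @param fn function category per star: `"Normal"`, `"Decreased"` or
#'   `"No function"`.
#' @param activity non-negative activity value per star.
#' @param haplotypes character matrix, one row per star, one column per
#'   panel variant (in panel order).
#' @param panel the [variant_panel] the haplotype columns refer to.
#' @return An object of class `allele_table`.
#' @export
allele_table <- function(star, fn, activity, haplotypes, panel) {
  stopifnot(inherits(panel, "variant_panel"))
  star <- as.character(star)
  fn <- as.character(fn)
  activity <- as.numeric(activity)
  haplotypes <- as.matrix(haplotypes)
  if (anyDuplicated(star))
    pgx_validation_error(sprintf(
      "duplicate star allele name(s): %s",
      paste(unique(star[duplicated(star)]), collapse = ", ")))
  if (!all(fn %in% ALLELE_FUNCTIONS))
    pgx_validation_error(sprintf(
      "unknown function label(s): %s (expected one of: %s)",
      paste(unique(fn[!fn %in% ALLELE_FUNCTIONS]), collapse = ", "),
      paste(ALLELE_FUNCTIONS, collapse = ", ")))
  if (anyNA(activity) || any(activity < 0))
    pgx_validation_error("activity values must be non-negative numbers")
  if (nrow(haplotypes) != length(star) || ncol(haplotypes) != length(panel))
    pgx_validation_error(sprintf(
      "haplotype matrix must be %d x %d (stars x panel variants); the allele columns must follow the panel's variant order",
      length(star), length(panel)))
  if (any(!nzchar(haplotypes)) || anyNA(haplotypes))
    pgx_validation_error("every haplotype allele must be a non-empty string")
  dimnames(haplotypes) <- list(star, panel$variant_ids)

  keys <- apply(haplotypes, 1L, hap_key)
  groups <- split(star, keys)
  ambiguous <- groups[vapply(groups, length, integer(1)) > 1L]
  if (length(ambiguous) > 0L) {
    warning(sprintf(
      "ambiguity group(s): the panel cannot distinguish %s",
      paste(vapply(ambiguous, paste, character(1), collapse = " | "),
            collapse = "; ")), call. = FALSE)
  }
  structure(list(
    stars = data.frame(star = star, fn = fn, activity = activity,
                       stringsAsFactors = FALSE),
    haplotypes = haplotypes,
    hap_keys = unname(keys),
    panel = panel,
    ambiguity_groups = unname(ambiguous)
  ), class = "allele_table")
}

ALLELE_FUNCTIONS <- c("Normal", "Decreased", "No function")

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %d star allele(s) over %d variant(s)\n",
              nrow(x$stars), length(x$panel)))
  print(cbind(x$stars, apply(x$haplotypes, 1L, paste, collapse = " ")),
        row.names = FALSE)
  invisible(x)
}

#' Read a star-allele definition file
#'
#' The file is CSV (or TSV) with columns: star name, function category,
#' activity value, then one allele column per panel variant *in the same
#' order as the genotype file*. A header row is required; its variant
#' labels, when they match none of the panel, are accepted as opaque, but a
#' wrong column count is always an error citing the ordering contract.
#'
#' @param path file path.
#' @param panel the [variant_panel] from the genotype table.
#' @param delimiter field delimiter; `NULL` auto-detects comma vs tab.
#' @return An [allele_table]. Duplicate haplotype vectors are loaded and
#'   flagged with an ambiguity-group warning.
#' @export
read_allele_definitions <- function(path, panel, delimiter = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  lines <- read_text_lines(path)
  if (length(lines) < 2L)
    pgx_parse_error("allele definition file must have a header and at least one star allele row")
  delimiter <- delimiter %||% detect_delimiter(lines[[1L]])
  fields <- lapply(strsplit(lines, delimiter, fixed = TRUE), trimws)
  ncol_exp <- 3L + length(panel)
  bad <- which(vapply(fields, length, integer(1)) != ncol_exp)
  if (length(bad) > 0L)
    pgx_format_error(sprintf(
      paste0("row %d: expected %d columns (star, function, activity, then one ",
             "allele per panel variant in the genotype file's order), found %d"),
      bad[[1L]], ncol_exp, length(fields[[bad[[1L]]]])))
  body <- fields[-1L]
  star <- vapply(body, `[[`, character(1), 1L)
  fn <- vapply(body, `[[`, character(1), 2L)
  activity_chr <- vapply(body, `[[`, character(1), 3L)
  activity <- suppressWarnings(as.numeric(activity_chr))
  if (anyNA(activity))
    pgx_validation_error(sprintf(
      "non-numeric activity value '%s' for star %s",
      activity_chr[which(is.na(activity))[1L]], star[which(is.na(activity))[1L]]))
  haplotypes <- do.call(rbind, lapply(body, function(f) f[-(1:3)]))
  allele_table(star, fn, activity, haplotypes, panel)
}

#' Write a star-allele definition file
#'
#' Inverse of [read_allele_definitions()].
#'
#' @param table an [allele_table].
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
write_allele_definitions <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "allele_table"))
  header <- paste(c("Star", "Function", "Activity", table$panel$variant_ids),
                  collapse = delimiter)
  rows <- vapply(seq_len(nrow(table$stars)), function(i) {
    paste(c(table$stars$star[[i]], table$stars$fn[[i]],
            format_activity(table$stars$activity[[i]]),
            table$haplotypes[i, ]), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(NULL)
}

# Per-variant allele sets used by the table (panel order).
table_allele_sets <- function(table) {
  lapply(seq_len(ncol(table$haplotypes)),
         function(j) sort_radix(unique(table$haplotypes[, j])))
}

format_activity <- function(x) {
  ifelse(is.na(x), "NA", sub("\\.?0+$", "", sprintf("%.4f", x)))
}
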