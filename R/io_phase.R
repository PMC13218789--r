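#' Write a PHASE-format input file
#'
#' Serializes a cohort in the classic PHASE 2.1.1 input dialect so that the
#' external PHASE program can be used as an alternative phasing engine:
#' line 1 the number of individuals, line 2 the number of loci, line 3 a
#' `"P"` line of locus positions (panel column indices, since variant ids
#' are opaque labels), line 4 one locus-type character per locus (`"S"` for
#' a biallelic single-character site, `"M"` otherwise), then for each
#' individual an ID line followed by two space-separated allele lines with
#' `"?"` at missing sites. Because input genotypes are unphased, the two
#' allele lines carry the canonical (sorted) order of each pair.
#'
#' @param panel a [variant_panel].
#' @param records list of [genotype_record] objects.
#' @param path output file path.
#' @export
write_phase_input <- function(panel, records, path) {
  stopifnot(inherits(panel, "variant_panel"))
  L <- length(panel)
  loc_types <- vapply(seq_len(L), function(j) {
    a <- panel$alleles_observed[[j]]
    if (length(a) <= 2L && all(nchar(a) == 1L)) "S" else "M"
  }, character(1))
  out <- c(
    as.character(length(records)),
    as.character(L),
    paste(c("P", seq_len(L)), collapse = " "),
    paste(loc_types, collapse = "")
  )
  for (r in records) {
    row1 <- vapply(r$calls, function(x) if (is_missing_call(x)) "?" else x[[1L]], character(1))
    row2 <- vapply(r$calls, function(x) if (is_missing_call(x)) "?" else x[[2L]], character(1))
    out <- c(out, r$sample_id, paste(row1, collapse = " "), paste(row2, collapse = " "))
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Read PHASE best-pair output
#'
#' Parses the best-pair section of a PHASE output file (the block between
#' `BEGIN BESTPAIRS*` and `END BESTPAIRS*`, or the whole file when no such
#' markers are present): per individual, an ID line followed by two
#' space-separated haplotype rows. PHASE ID lines of the form `"0 ID"` are
#' accepted; the last whitespace token is taken as the sample ID.
#'
#' @param path file path.
#' @param panel the [variant_panel]; haplotype rows must have one allele
#'   per panel variant.
#' @param n_expected optional expected number of individuals; a mismatch is
#'   a format error.
#' @return A list, one element per individual:
#'   `list(sample_id, h1, h2)` with `h1`/`h2` character allele vectors in
#'   panel order, canonically ordered (`h1 <= h2`).
#' @export
read_phase_output <- function(path, panel, n_expected = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  lines <- trimws(readLines(path, warn = FALSE))
  begin <- grep("^BEGIN BESTPAIRS", lines)
  if (length(begin) > 0L) {
    end <- grep("^END BESTPAIRS", lines)
    if (length(end) == 0L || end[[1L]] <= begin[[1L]])
      pgx_format_error("unterminated BESTPAIRS block")
    lines <- lines[(begin[[1L]] + 1L):(end[[1L]] - 1L)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L)
    pgx_format_error(sprintf(
      "best-pair section has %d non-empty lines; expected 3 per individual (ID, two haplotype rows)",
      length(lines)))
  n <- length(lines) %/% 3L
  if (!is.null(n_expected) && n != n_expected)
    pgx_format_error(sprintf(
      "best-pair section lists %d individual(s); expected %d", n, n_expected))
  L <- length(panel)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id_line <- lines[[3L * i - 2L]]
    toks <- strsplit(id_line, "[[:space:]]+")[[1L]]
    sample_id <- toks[[length(toks)]]
    sample_id <- sub("^#", "", sample_id)
    h1 <- strsplit(lines[[3L * i - 1L]], "[[:space:]]+")[[1L]]
    h2 <- strsplit(lines[[3L * i]], "[[:space:]]+")[[1L]]
    if (length(h1) != L || length(h2) != L)
      pgx_format_error(sprintf(
        "individual %s: haplotype rows must have %d alleles", sample_id, L))
    pair <- canonical_pair(h1, h2)
    out[[i]] <- list(sample_id = sample_id, h1 = pair[[1L]], h2 = pair[[2L]])
  }
  out
}

# Order a haplotype pair canonically (lexicographic over allele vectors,
# radix/byte order, locale-independent).
canonical_pair <- function(h1, h2) {
  r <- key_ranks(c(hap_key(h1), hap_key(h2)))
  if (r[[1L]] <= r[[2L]]) list(h1, h2) else list(h2, h1)
}
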