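# Translate phased haplotypes into star-allele names by exact matching
# against the allele definition table. Matching is a pure function of the
# haplotype and the table; no frequency information is consulted.

#' Match a haplotype against the star-allele definition table
#'
#' Exact site-wise comparison against every table row. All matching star
#' names are returned: more than one name means the panel cannot
#' distinguish the stars (an ambiguity group, rendered `"*2|*35"`). No
#' match is a value (`NO_CALL`, rendered `"*?"`), never an error — an
#' off-table haplotype is *not* defaulted to *1, which would fabricate a
#' normal-function call.
#'
#' @param h character allele vector, one entry per panel variant.
#' @param table an [allele_table].
#' @return A `star_match`: `star_names` (possibly empty character vector),
#'   `ambiguous` flag, rendered `label`, and `activity` (NA when no call,
#'   or when an ambiguity group's members disagree on activity).
#' @export
match_haplotype <- function(h, table) {
  stopifnot(inherits(table, "allele_table"))
  if (length(h) != length(table$panel))
    pgx_validation_error(sprintf(
      "haplotype has %d alleles; the panel has %d variants",
      length(h), length(table$panel)))
  hits <- which(table$hap_keys == hap_key(h))
  names <- table$stars$star[hits]
  star_match(names, table$stars$activity[hits])
}

star_match <- function(names, activities) {
  names <- names[order(star_sort_key(names), names, method = "radix")]
  ambiguous <- length(names) > 1L
  if (length(names) == 0L) {
    label <- "*?"
    activity <- NA_real_
  } else {
    label <- paste(names, collapse = "|")
    activity <- if (length(unique(activities)) == 1L) activities[[1L]] else NA_real_
  }
  structure(list(star_names = names, ambiguous = ambiguous,
                 label = label, activity = activity),
            class = "star_match")
}

# The *5 (gene deletion) pseudo-match used by the CNV rules: activity 0 by
# definition of gene absence.
star5_match <- function() {
  structure(list(star_names = "*5", ambiguous = FALSE,
                 label = "*5", activity = 0),
            class = "star_match")
}

is_no_call <- function(m) length(m$star_names) == 0L

#' @export
print.star_match <- function(x, ...) {
  cat(sprintf("<star_match> %s (activity %s)\n", x$label,
              if (is.na(x$activity)) "NA" else format(x$activity)))
  invisible(x)
}

#' Call a diplotype from a phased haplotype pair
#'
#' Matches each haplotype of a [phase_cohort()] pair against the table and
#' renders the diplotype string with the two calls sorted by star number
#' (`"*1/*4"`, never `"*4/*1"`; a no-call renders as `"*?"` and sorts
#' last).
#'
#' @param pair a `phased_pair`.
#' @param table an [allele_table].
#' @return List with `match1`, `match2` (in rendered order), `diplotype`
#'   string and `no_call` flag.
#' @export
call_diplotype <- function(pair, table) {
  m1 <- match_haplotype(pair$h1, table)
  m2 <- match_haplotype(pair$h2, table)
  ord <- order(c(star_sort_key(m1$label), star_sort_key(m2$label)),
               c(m1$label, m2$label), method = "radix")
  ms <- list(m1, m2)[ord]
  list(match1 = ms[[1L]], match2 = ms[[2L]],
       diplotype = render_diplotype(ms[[1L]]$label, ms[[2L]]$label),
       no_call = is_no_call(m1) || is_no_call(m2))
}

render_diplotype <- function(label1, label2) paste(label1, label2, sep = "/")

#' Parse a diplotype string
#'
#' Splits a rendered diplotype (`"*1/*4"`, `"*1x2/*1"`) back into its two
#' star labels as an unordered pair (sorted by star number).
#'
#' @param s diplotype string.
#' @return Character vector of the two labels.
#' @export
parse_diplotype <- function(s) {
  labels <- strsplit(s, "/", fixed = TRUE)[[1L]]
  if (length(labels) != 2L)
    pgx_parse_error(sprintf("'%s' is not a diplotype string", s))
  labels[order(star_sort_key(labels), labels, method = "radix")]
}

# Numeric sort key for star labels: the leading number of the first
# alternative ("*2|*35" -> 2, "*1x2" -> 1); "*?" sorts last.
star_sort_key <- function(labels) {
  vapply(labels, function(lab) {
    first <- strsplit(lab, "|", fixed = TRUE)[[1L]][[1L]]
    num <- sub("^\\*([0-9]+).*$", "\\1", first)
    if (grepl("^[0-9]+$", num)) as.numeric(num) else Inf
  }, numeric(1), USE.NAMES = FALSE)
}
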