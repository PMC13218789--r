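#' Variant panel
#'
#' An ordered set of assayed variant identifiers. The order of `variant_ids`
#' is the column-order contract shared by the genotype table and the allele
#' definition file: every haplotype vector and genotype record is interpreted
#' in this order, and it is immutable after load. Variant identifiers are
#' opaque labels (e.g. `"1846G>A"` or rsIDs); no genomic arithmetic is ever
#' performed on them.
#'
#' @param variant_ids character vector of unique, non-empty variant labels.
#' @param alleles_observed optional named list (one entry per variant, in
#'   panel order) of allele strings seen at that variant.
#' @return An object of class `variant_panel`.
#' @export
variant_panel <- function(variant_ids, alleles_observed = NULL) {
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) == 0L || any(!nzchar(variant_ids)))
    pgx_validation_error("variant panel must have at least one non-empty variant id")
  if (anyDuplicated(variant_ids))
    pgx_validation_error(sprintf(
      "duplicate variant id(s) in panel: %s",
      paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", ")))
  if (is.null(alleles_observed)) {
    alleles_observed <- rep(list(character(0)), length(variant_ids))
  }
  if (length(alleles_observed) != length(variant_ids))
    pgx_validation_error("alleles_observed must have one entry per variant")
  alleles_observed <- lapply(alleles_observed, function(a) sort_radix(unique(as.character(a))))
  if (any(vapply(alleles_observed, function(a) any(!nzchar(a)), logical(1))))
    pgx_validation_error("empty allele string in alleles_observed")
  names(alleles_observed) <- variant_ids
  structure(list(variant_ids = variant_ids, alleles_observed = alleles_observed),
            class = "variant_panel")
}

#' @export
length.variant_panel <- function(x) length(x$variant_ids)

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d variant(s): %s\n",
              length(x), paste(x$variant_ids, collapse = ", ")))
  invisible(x)
}

# Merge extra observed alleles (e.g. from an allele definition table) into a
# panel's per-variant allele sets. Returns a new panel; order is unchanged.
panel_add_alleles <- function(panel, allele_list) {
  stopifnot(inherits(panel, "variant_panel"))
  obs <- panel$alleles_observed
  for (j in seq_along(obs)) {
    obs[[j]] <- sort_radix(unique(c(obs[[j]], allele_list[[j]])))
  }
  variant_panel(panel$variant_ids, obs)
}

#' Construct a genotype record
#'
#' One sample's unordered allele pairs across a panel. Each call is either a
#' length-2 character vector (canonicalized to sorted order, since targeted
#' assays carry no phase) or `NA` for a missing call.
#'
#' @param sample_id non-empty sample identifier.
#' @param calls list, one element per panel variant: `c(a, b)` or `NA`.
#' @return An object of class `genotype_record`.
#' @export
genotype_record <- function(sample_id, calls) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    pgx_validation_error("sample_id must be a non-empty string")
  calls <- lapply(calls, function(x) {
    if (length(x) == 1L && is.na(x)) return(NA)
    x <- as.character(x)
    if (length(x) != 2L || any(!nzchar(x)) || anyNA(x))
      pgx_validation_error(sprintf(
        "sample %s: a genotype call must be an allele pair or missing", sample_id))
    sort_radix(x)
  })
  structure(list(sample_id = sample_id, calls = calls), class = "genotype_record")
}

# Character key identifying a record's genotype pattern (used to collapse
# duplicate patterns before EM).
genotype_pattern_key <- function(record) {
  paste(vapply(record$calls, function(x) {
    if (is_missing_call(x)) "?" else paste(x, collapse = "|")
  }, character(1)), collapse = .HAP_SEP)
}
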