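# Copy-number adjustment of called diplotypes, activity scoring, and
# CPIC-style metabolizer phenotype classification.

#' Default activity-score thresholds
#'
#' The CPIC consensus mapping from activity score (AS) to CYP2D6
#' metabolizer phenotype: PM at AS = 0, IM on (0, 1.25), NM on
#' [1.25, 2.25], UM above 2.25. These are configuration values — override
#' them with [read_thresholds()] — never constants baked into the
#' classification logic.
#'
#' @return A validated `phenotype_thresholds` data frame with columns
#'   `category`, `lower`, `upper`, `lower_open`, `upper_open`.
#' @export
default_thresholds <- function() {
  validate_thresholds(data.frame(
    category = c("PM", "IM", "NM", "UM"),
    lower = c(0, 0, 1.25, 2.25),
    upper = c(0, 1.25, 2.25, Inf),
    lower_open = c(FALSE, TRUE, FALSE, TRUE),
    upper_open = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ))
}

PHENOTYPE_ORDER <- c("PM", "IM", "NM", "UM")

#' Validate phenotype thresholds
#'
#' Checks that the intervals form an exhaustive, non-overlapping,
#' left-to-right ordered partition of `[0, Inf)` over the categories
#' PM, IM, NM, UM (a suffix may be merged away, but PM must contain
#' AS = 0). Malformed thresholds fail here, at load time, never during
#' classification.
#'
#' @param thresholds data frame with columns `category`, `lower`, `upper`,
#'   `lower_open`, `upper_open`.
#' @return The thresholds, with class `phenotype_thresholds`.
#' @export
validate_thresholds <- function(thresholds) {
  req <- c("category", "lower", "upper", "lower_open", "upper_open")
  if (!all(req %in% names(thresholds)))
    pgx_config_error(sprintf("thresholds must have columns: %s", paste(req, collapse = ", ")))
  # a closed lower bound starts earlier than an open one at the same value
  t <- thresholds[order(thresholds$lower, thresholds$lower_open), , drop = FALSE]
  if (!all(t$category %in% PHENOTYPE_ORDER) || anyDuplicated(t$category))
    pgx_config_error("threshold categories must be distinct members of PM, IM, NM, UM")
  if (!identical(t$category, intersect(PHENOTYPE_ORDER, t$category)))
    pgx_config_error("threshold categories must appear in PM -> UM order of increasing AS")
  if (t$lower[[1L]] != 0 || t$lower_open[[1L]])
    pgx_config_error("the first interval must start at AS = 0 (closed)")
  if (t$category[[1L]] != "PM")
    pgx_config_error("AS = 0 must classify as PM")
  if (is.finite(t$upper[[nrow(t)]]))
    pgx_config_error("the last interval must extend to infinity")
  if (any(t$upper < t$lower))
    pgx_config_error("an interval's upper bound is below its lower bound")
  degenerate <- t$lower == t$upper & (t$lower_open | t$upper_open)
  if (any(degenerate))
    pgx_config_error("an empty interval (open point) in the thresholds")
  if (nrow(t) > 1L) {
    for (i in 2:nrow(t)) {
      if (t$lower[[i]] != t$upper[[i - 1L]] ||
          identical(t$lower_open[[i]], t$upper_open[[i - 1L]]))
        pgx_config_error(sprintf(
          "intervals %s and %s do not tile [0, Inf): adjacent bounds must meet with exactly one side closed",
          t$category[[i - 1L]], t$category[[i]]))
    }
  }
  rownames(t) <- NULL
  class(t) <- c("phenotype_thresholds", "data.frame")
  t
}

#' Read a phenotype-threshold configuration file
#'
#' CSV with columns `category,lower,upper,lower_open,upper_open`
#' (booleans as `TRUE`/`FALSE`; `upper` may be `Inf`). The result is
#' validated as a partition of `[0, Inf)`.
#'
#' @param path file path.
#' @return A `phenotype_thresholds` object.
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("lower", "upper")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("lower_open", "upper_open")) df[[col]] <- as.logical(df[[col]])
  if (anyNA(df$lower) || anyNA(df$upper) || anyNA(df$lower_open) || anyNA(df$upper_open))
    pgx_config_error("thresholds file contains non-numeric bounds or non-boolean openness flags")
  validate_thresholds(df)
}

#' Apply copy-number rules to a called diplotype
#'
#' Implements the gene-dosage rules: two copies (the default) leave the
#' call unchanged; one copy is a gene deletion, so the second star allele
#' is replaced with *5 (gene absence) — a heterozygous genotype with one
#' reported copy is kept as called and flagged `hemizygosity_conflict`
#' (likely a CNV-assay error); zero copies extrapolate to a *5/*5
#' homozygous deletion (flagged); three or more copies with identical star
#' calls infer the duplicated allele and render it `"Ax(n-1)/A"`, while
#' different star calls make the duplicated allele unidentifiable and the
#' result indeterminate.
#'
#' @param matches result of [call_diplotype()].
#' @param pair the underlying `phased_pair` (used to test haplotype
#'   identity under one reported copy).
#' @param cnv integer copy number, >= 0.
#' @return An `adjusted_diplotype`: ordered `match1`/`match2`, rendered
#'   `labels` and `diplotype`, `kind` (one of `"normal"`, `"deletion"`,
#'   `"homozygous_deletion"`, `"duplication"`, `"indeterminate_dup"`),
#'   `cnv`, and `flags`. Conflicts are flags, never exceptions.
#' @export
apply_cnv <- function(matches, pair, cnv) {
  if (cnv < 0) pgx_validation_error("copy number must be >= 0")
  flags <- character(0)
  m1 <- matches$match1; m2 <- matches$match2
  kind <- "normal"
  if (cnv == 2L) {
    labels <- c(m1$label, m2$label)
  } else if (cnv == 1L) {
    same_hap <- !is.na(pair$h1[[1L]]) && identical(pair$h1, pair$h2)
    if (same_hap) {
      kind <- "deletion"
      m2 <- star5_match()
      labels <- c(m1$label, m2$label)
    } else {
      labels <- c(m1$label, m2$label)
      flags <- c(flags, "hemizygosity_conflict")
    }
  } else if (cnv == 0L) {
    kind <- "homozygous_deletion"
    m1 <- star5_match(); m2 <- star5_match()
    labels <- c("*5", "*5")
    flags <- c(flags, "homozygous_deletion_assumed")
  } else {  # cnv >= 3
    identical_call <- !matches$no_call && identical(m1$label, m2$label)
    if (identical_call) {
      kind <- "duplication"
      labels <- c(paste0(m1$label, "x", cnv - 1L), m2$label)
    } else {
      kind <- "indeterminate_dup"
      labels <- c(m1$label, m2$label)
      flags <- c(flags, "indeterminate_duplication")
    }
  }
  structure(list(match1 = m1, match2 = m2, labels = labels,
                 diplotype = render_diplotype(labels[[1L]], labels[[2L]]),
                 kind = kind, cnv = as.integer(cnv), flags = flags),
            class = "adjusted_diplotype")
}

#' Compute the activity score of a CNV-adjusted diplotype
#'
#' The activity score (AS) is the sum of the activity values over all gene
#' copies: with at most two copies, `act(allele1) + act(allele2)` (*5
#' contributes 0); a homozygous duplication to `n` copies of allele A
#' scores `n * act(A)`; an indeterminate duplication (different alleles,
#' unknown duplicated copy) is reported as indeterminate with bounds
#' `[a + b + (n-2) * min(a, b), a + b + (n-2) * max(a, b)]`. Any no-call
#' haplotype makes the AS indeterminate.
#'
#' @param adjusted an `adjusted_diplotype` from [apply_cnv()].
#' @return An `activity_score` object: `value` (numeric, or `NA` when
#'   indeterminate), `indeterminate` flag, optional `bounds`, and `flags`.
#' @export
activity_score <- function(adjusted) {
  stopifnot(inherits(adjusted, "adjusted_diplotype"))
  m1 <- adjusted$match1; m2 <- adjusted$match2
  flags <- character(0)
  if (is_no_call(m1) || is_no_call(m2)) {
    return(new_activity_score(NA_real_, TRUE, NULL, "no_call"))
  }
  if (is.na(m1$activity) || is.na(m2$activity)) {
    # ambiguity group whose members disagree on activity
    return(new_activity_score(NA_real_, TRUE, NULL, "ambiguous_activity"))
  }
  a1 <- m1$activity; a2 <- m2$activity
  switch(adjusted$kind,
    normal = ,
    deletion = ,
    homozygous_deletion = new_activity_score(a1 + a2, FALSE, NULL, flags),
    duplication = new_activity_score(adjusted$cnv * a1, FALSE, NULL, flags),
    indeterminate_dup = {
      extra <- adjusted$cnv - 2L
      bounds <- c(a1 + a2 + extra * min(a1, a2), a1 + a2 + extra * max(a1, a2))
      new_activity_score(NA_real_, TRUE, bounds, flags)
    },
    pgx_validation_error(sprintf("unknown adjusted diplotype kind '%s'", adjusted$kind))
  )
}

new_activity_score <- function(value, indeterminate, bounds, flags) {
  structure(list(value = value, indeterminate = indeterminate,
                 bounds = bounds, flags = flags),
            class = "activity_score")
}

#' @export
print.activity_score <- function(x, ...) {
  if (x$indeterminate) {
    cat("<activity_score> indeterminate",
        if (!is.null(x$bounds)) sprintf(" [%g, %g]", x$bounds[[1L]], x$bounds[[2L]]) else "",
        "\n", sep = "")
  } else {
    cat(sprintf("<activity_score> %g\n", x$value))
  }
  invisible(x)
}

#' Classify a metabolizer phenotype from an activity score
#'
#' Interval lookup of the AS in the threshold partition. An indeterminate
#' AS classifies as `"Indeterminate"` unless both of its bounds fall in the
#' same category, in which case that category is returned with a
#' `"bounded"` note attribute (the phenotype is known even though the exact
#' AS is not).
#'
#' @param as_value an `activity_score` object, or a plain non-negative
#'   number.
#' @param thresholds a `phenotype_thresholds` object.
#' @return The category string (`"PM"`, `"IM"`, `"NM"`, `"UM"` or
#'   `"Indeterminate"`), possibly with a `note` attribute.
#' @export
classify_phenotype <- function(as_value, thresholds = default_thresholds()) {
  stopifnot(inherits(thresholds, "phenotype_thresholds"))
  if (is.numeric(as_value)) {
    return(lookup_category(as_value, thresholds))
  }
  stopifnot(inherits(as_value, "activity_score"))
  if (!as_value$indeterminate) return(lookup_category(as_value$value, thresholds))
  if (!is.null(as_value$bounds)) {
    lo <- lookup_category(as_value$bounds[[1L]], thresholds)
    hi <- lookup_category(as_value$bounds[[2L]], thresholds)
    if (identical(lo, hi)) {
      return(structure(lo, note = sprintf(
        "AS indeterminate but both bounds [%g, %g] fall in %s",
        as_value$bounds[[1L]], as_value$bounds[[2L]], lo)))
    }
  }
  "Indeterminate"
}

lookup_category <- function(x, t) {
  if (is.na(x)) return("Indeterminate")
  if (x < 0) pgx_validation_error("activity score must be >= 0")
  for (i in seq_len(nrow(t))) {
    in_lower <- x > t$lower[[i]] || (!t$lower_open[[i]] && x == t$lower[[i]])
    in_upper <- x < t$upper[[i]] || (!t$upper_open[[i]] && x == t$upper[[i]])
    if (in_lower && in_upper) return(t$category[[i]])
  }
  "Indeterminate"  # unreachable for valid thresholds
}
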