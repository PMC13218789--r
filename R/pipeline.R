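# End-to-end orchestration: read -> EM phasing -> star calling -> CNV
# adjustment -> activity score -> phenotype -> report.

#' Run the full diplotyping pipeline
#'
#' Executes the three-stage workflow on a cohort: (i) load the genotype
#' table, the star-allele definition file and the optional copy-number
#' table; (ii) reconstruct haplotypes jointly across all individuals
#' ([em_estimate()] then [phase_cohort()]); (iii) assign star alleles,
#' apply the copy-number rules, compute activity scores and classify
#' metabolizer phenotypes. Single-sample runs are legal but joint phasing
#' is uninformative at n = 1, which is logged as a warning.
#'
#' The same inputs and seed always produce a byte-identical report.
#' Output files are written atomically: on any error no partial output is
#' left behind.
#'
#' @param genotypes path to the genotype table, or an in-memory
#'   `list(panel, records)` as returned by [read_genotype_table()].
#' @param alleles path to the allele definition file, or an
#'   [allele_table].
#' @param cnv optional path to a copy-number table, or a data frame
#'   (`sample_id`, `copies`); absent samples default to two copies.
#' @param thresholds optional path to a threshold config file, or a
#'   `phenotype_thresholds` object; defaults to [default_thresholds()].
#' @param out optional path for the CSV report.
#' @param summary optional path for a machine-readable JSON run summary.
#' @param delimiter,genotype_sep,missing_tokens input dialect options, as
#'   in [read_genotype_table()].
#' @param seed,n_restarts,tol,max_iter,het_cap phasing options, as in
#'   [em_estimate()].
#' @param verbose log progress to stderr.
#' @return Invisibly, a list: `report` (the per-sample data frame),
#'   `freqs` (the `hap_freq_set`), `pairs` (phased pairs), `table`,
#'   `thresholds` and `summary` (the run-summary list).
#' @export
run_pipeline <- function(genotypes, alleles, cnv = NULL, thresholds = NULL,
                         out = NULL, summary = NULL, delimiter = NULL,
                         genotype_sep = "/", missing_tokens = c("./.", ""),
                         seed = 1L, n_restarts = 3L, tol = 1e-8,
                         max_iter = 1000L, het_cap = 15L, verbose = FALSE) {
  log_msg <- function(...) if (verbose) message(sprintf(...))

  gt <- if (is.character(genotypes)) {
    read_genotype_table(genotypes, delimiter = delimiter,
                        genotype_sep = genotype_sep,
                        missing_tokens = missing_tokens)
  } else genotypes
  if (!inherits(gt$panel, "variant_panel"))
    pgx_validation_error("genotypes must be a file path or a list(panel, records)")
  table <- if (is.character(alleles)) {
    read_allele_definitions(alleles, gt$panel, delimiter = delimiter)
  } else alleles
  if (!inherits(table, "allele_table"))
    pgx_validation_error("alleles must be a file path or an allele_table")
  cnv_df <- if (is.character(cnv)) read_cnv_table(cnv) else cnv
  thr <- if (is.character(thresholds)) read_thresholds(thresholds)
         else thresholds %||% default_thresholds()

  n <- length(gt$records)
  log_msg("cohort: %d sample(s), %d variant(s), %d star allele(s)",
          n, length(gt$panel), nrow(table$stars))
  if (n == 1L)
    warning("joint phasing is uninformative for a single-sample cohort; ",
            "phase posteriors reflect only within-sample ambiguity",
            call. = FALSE)

  # missing-site expansion draws on alleles seen in the cohort AND in the
  # definition table
  wildcards <- panel_add_alleles(gt$panel, table_allele_sets(table))$alleles_observed
  freqs <- em_estimate(gt$records, wildcards = wildcards, tol = tol,
                       max_iter = max_iter, n_restarts = n_restarts,
                       seed = seed, het_cap = het_cap)
  log_msg("EM: %d support haplotype(s), loglik %.4f, %d iteration(s), %s",
          nrow(freqs$haplotypes), freqs$loglik, freqs$n_iter,
          if (freqs$converged) "converged" else "NOT converged")
  pairs <- phase_cohort(gt$records, freqs, wildcards = wildcards,
                        het_cap = het_cap)

  copies <- cnv_for_samples(vapply(gt$records, `[[`, character(1), "sample_id"),
                            cnv_df)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- assemble_call(pairs[[i]], copies[[i]], table, thr)
  }
  report <- do.call(rbind, rows)
  class(report) <- c("diplotype_calls", "data.frame")

  flag_counts <- flag_count_table(report$flags)
  summary_list <- list(
    n_samples = n,
    n_variants = length(gt$panel),
    n_stars = nrow(table$stars),
    n_support_haplotypes = nrow(freqs$haplotypes),
    em = list(loglik = freqs$loglik, n_iter = freqs$n_iter,
              converged = freqs$converged,
              restart_logliks = freqs$restart_logliks),
    phenotype_counts = as.list(table(report$phenotype)),
    flag_counts = flag_counts,
    seed = seed
  )
  log_msg("flags: %s",
          if (length(flag_counts)) paste(names(flag_counts), unlist(flag_counts),
                                         sep = "=", collapse = ", ") else "none")

  if (!is.null(out)) atomic_write(out, function(p) write_report(report, p))
  if (!is.null(summary))
    atomic_write(summary, function(p)
      jsonlite::write_json(summary_list, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
  invisible(list(report = report, freqs = freqs, pairs = pairs,
                 table = table, thresholds = thr, summary = summary_list))
}

# One report row for one sample.
assemble_call <- function(pair, cnv, table, thresholds) {
  if ("all_missing" %in% pair$flags) {
    if (cnv == 0L) {
      adjusted <- structure(list(match1 = star5_match(), match2 = star5_match(),
                                 labels = c("*5", "*5"), diplotype = "*5/*5",
                                 kind = "homozygous_deletion", cnv = 0L,
                                 flags = c("all_missing", "homozygous_deletion_assumed")),
                            class = "adjusted_diplotype")
      as_obj <- activity_score(adjusted)
    } else {
      adjusted <- list(labels = c("*?", "*?"), diplotype = "*?/*?",
                       flags = "all_missing")
      as_obj <- new_activity_score(NA_real_, TRUE, NULL, "no_call")
    }
  } else {
    matches <- call_diplotype(pair, table)
    adjusted <- apply_cnv(matches, pair, cnv)
    as_obj <- activity_score(adjusted)
    if (matches$no_call) adjusted$flags <- c(adjusted$flags, "no_call")
    if (matches$match1$ambiguous || matches$match2$ambiguous)
      adjusted$flags <- c(adjusted$flags, "ambiguous_group")
  }
  phen <- classify_phenotype(as_obj, thresholds)
  note <- attr(phen, "note")
  flags <- sort_radix(unique(c(pair$flags, adjusted$flags, as_obj$flags,
                               if (!is.null(note)) "phenotype_from_bounds")))
  data.frame(
    sample_id = pair$sample_id,
    hap1 = adjusted$labels[[1L]],
    hap2 = adjusted$labels[[2L]],
    cnv = as.integer(cnv),
    diplotype = adjusted$diplotype,
    activity_score = format_as(if (as_obj$indeterminate) NA_real_ else as_obj$value),
    phenotype = unclass_note(phen),
    phase_posterior = format_posterior(pair$posterior),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

flag_count_table <- function(flags_col) {
  f <- unlist(strsplit(flags_col[nzchar(flags_col)], ";", fixed = TRUE))
  if (length(f) == 0L) return(list())
  as.list(table(f))
}

# Write via a sibling temp file + rename so failures never leave partial
# output.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Lint pipeline inputs
#'
#' Checks the mutual consistency of a genotype table, an allele definition
#' file and an optional CNV table without running the pipeline: column
#' order/shape, genotype alleles never used by any star definition, and
#' CNV sample IDs absent from the genotype table.
#'
#' @param genotypes,alleles,cnv,delimiter as in [run_pipeline()].
#' @return Character vector of human-readable findings (empty when clean).
#' @export
validate_inputs <- function(genotypes, alleles, cnv = NULL, delimiter = NULL) {
  gt <- if (is.character(genotypes))
    read_genotype_table(genotypes, delimiter = delimiter) else genotypes
  table <- if (is.character(alleles))
    read_allele_definitions(alleles, gt$panel, delimiter = delimiter) else alleles
  findings <- character(0)
  tab_sets <- table_allele_sets(table)
  for (j in seq_along(gt$panel$variant_ids)) {
    extra <- setdiff(gt$panel$alleles_observed[[j]], tab_sets[[j]])
    if (length(extra) > 0L)
      findings <- c(findings, sprintf(
        "variant %s: allele(s) %s appear in the genotype table but in no star definition",
        gt$panel$variant_ids[[j]], paste(extra, collapse = ", ")))
  }
  if (!is.null(cnv)) {
    cnv_df <- if (is.character(cnv)) read_cnv_table(cnv) else cnv
    ids <- vapply(gt$records, `[[`, character(1), "sample_id")
    orphan <- setdiff(cnv_df$sample_id, ids)
    if (length(orphan) > 0L)
      findings <- c(findings, sprintf(
        "CNV table sample(s) absent from the genotype table: %s",
        paste(orphan, collapse = ", ")))
  }
  findings
}
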