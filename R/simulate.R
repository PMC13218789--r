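# Synthetic-cohort generator with known truth: draws diplotypes under
# Hardy-Weinberg from a star-allele frequency model, materializes genotype
# calls at the panel's variants, and computes the truth through the same
# copy-number and scoring rules the pipeline applies. Haplotypes are drawn
# only from the definition table (calling is closed over the reference
# file); a novel-haplotype toggle injects off-table vectors to exercise
# no-call paths.

#' Build and validate a simulation configuration
#'
#' @param star_freqs named numeric vector of star-allele frequencies
#'   (must sum to 1; every name must exist in the table the config is used
#'   with).
#' @param n_samples number of samples to simulate (>= 1).
#' @param missing_rate per-site probability of masking a call, in `[0, 1)`.
#' @param cnv_spec named numeric vector: copy number (as name) ->
#'   probability; defaults to everyone carrying two copies.
#' @param novel_rate per-haplotype probability of replacing a drawn
#'   haplotype with an off-table vector (exercises NO_CALL handling).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(star_freqs, n_samples, missing_rate = 0,
                              cnv_spec = c("2" = 1), novel_rate = 0,
                              seed = 1L) {
  if (is.null(names(star_freqs)) || any(!nzchar(names(star_freqs))))
    pgx_validation_error("star_freqs must be a named vector")
  if (abs(sum(star_freqs) - 1) > 1e-9)
    pgx_validation_error("star allele frequencies must sum to 1")
  if (any(star_freqs < 0))
    pgx_validation_error("star allele frequencies must be non-negative")
  if (n_samples < 1L)
    pgx_validation_error("n_samples must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    pgx_validation_error("missing_rate must be in [0, 1)")
  if (is.null(names(cnv_spec)) || abs(sum(cnv_spec) - 1) > 1e-9 ||
      any(cnv_spec < 0) || any(!grepl("^[0-9]+$", names(cnv_spec))))
    pgx_validation_error("cnv_spec must map non-negative integer copy numbers to probabilities summing to 1")
  structure(list(star_freqs = star_freqs, n_samples = as.integer(n_samples),
                 missing_rate = missing_rate, cnv_spec = cnv_spec,
                 novel_rate = novel_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic cohort with known truth
#'
#' Per sample: a copy number is drawn from `cnv_spec`; star alleles are
#' drawn i.i.d. from `star_freqs` (Hardy-Weinberg pairing) — two for two or
#' more copies, one (observed as apparently homozygous) for a single copy,
#' none for a homozygous deletion, whose calls are all missing; the star
#' haplotype vectors are materialized from the table and collapsed to
#' unordered genotype calls; sites are masked i.i.d. at `missing_rate`.
#' The truth diplotype, activity score and phenotype are computed through
#' [apply_cnv()], [activity_score()] and [classify_phenotype()], so truth
#' reflects exactly what the scoring rules can know (e.g. a heterozygous
#' duplication is truly indeterminate).
#'
#' @param config a [simulation_config()].
#' @param table the [allele_table] to draw haplotypes from.
#' @param thresholds phenotype thresholds for the truth labels.
#' @return A list: `panel`, `records` (list of [genotype_record]), `cnv`
#'   (data frame `sample_id`, `copies`), and `truth` (data frame
#'   `sample_id`, `star1`, `star2`, `diplotype`, `activity_score`,
#'   `phenotype`, `cnv`).
#' @export
generate_cohort <- function(config, table, thresholds = default_thresholds()) {
  stopifnot(inherits(config, "simulation_config"), inherits(table, "allele_table"))
  missing_star <- setdiff(names(config$star_freqs), table$stars$star)
  if (length(missing_star) > 0L)
    pgx_validation_error(sprintf(
      "star(s) in the simulation config absent from the table: %s",
      paste(missing_star, collapse = ", ")))
  n <- config$n_samples
  L <- length(table$panel)
  star_idx <- match(names(config$star_freqs), table$stars$star)
  copy_levels <- as.integer(names(config$cnv_spec))

  with_seed(config$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    copies <- copy_levels[sample.int(length(copy_levels), n, replace = TRUE,
                                     prob = config$cnv_spec)]
    records <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      cnv <- copies[[i]]
      if (cnv == 0L) {
        records[[i]] <- genotype_record(sample_ids[[i]], rep(list(NA), L))
        truth[[i]] <- data.frame(
          sample_id = sample_ids[[i]], star1 = "*5", star2 = "*5",
          diplotype = "*5/*5", activity_score = 0, phenotype = "PM",
          cnv = cnv, stringsAsFactors = FALSE)
        next
      }
      n_draw <- if (cnv == 1L) 1L else 2L
      drawn <- star_idx[sample.int(length(star_idx), n_draw, replace = TRUE,
                                   prob = config$star_freqs)]
      h1 <- table$haplotypes[drawn[[1L]], ]
      h2 <- if (n_draw == 2L) table$haplotypes[drawn[[2L]], ] else h1
      if (config$novel_rate > 0) {
        if (stats::runif(1) < config$novel_rate) h1 <- perturb_haplotype(h1, table)
        if (n_draw == 2L && stats::runif(1) < config$novel_rate)
          h2 <- perturb_haplotype(h2, table)
      }
      calls <- lapply(seq_len(L), function(j) sort_radix(c(h1[[j]], h2[[j]])))
      records[[i]] <- genotype_record(sample_ids[[i]], calls)
      truth[[i]] <- truth_row(sample_ids[[i]], h1, h2, cnv, table, thresholds)
    }
    if (config$missing_rate > 0) {
      for (i in seq_len(n)) {
        if (copies[[i]] == 0L) next
        mask <- stats::runif(L) < config$missing_rate
        if (any(mask)) {
          calls <- records[[i]]$calls
          calls[mask] <- list(NA)
          records[[i]] <- genotype_record(sample_ids[[i]], calls)
        }
      }
    }
    list(panel = table$panel,
         records = records,
         cnv = data.frame(sample_id = sample_ids, copies = copies,
                          stringsAsFactors = FALSE),
         truth = do.call(rbind, truth))
  })
}

# Truth for one sample: call the true haplotype pair against the table and
# push it through the copy-number and scoring rules.
truth_row <- function(sample_id, h1, h2, cnv, table, thresholds) {
  pair <- canonical_pair(h1, h2)
  ppair <- structure(list(sample_id = sample_id, h1 = pair[[1L]],
                          h2 = pair[[2L]], posterior = 1, n_resolutions = 1L,
                          flags = character(0)), class = "phased_pair")
  matches <- call_diplotype(ppair, table)
  adjusted <- apply_cnv(matches, ppair, cnv)
  as_obj <- activity_score(adjusted)
  phen <- unclass_note(classify_phenotype(as_obj, thresholds))
  data.frame(sample_id = sample_id,
             star1 = adjusted$labels[[1L]], star2 = adjusted$labels[[2L]],
             diplotype = adjusted$diplotype,
             activity_score = if (as_obj$indeterminate) NA_real_ else as_obj$value,
             phenotype = phen, cnv = cnv, stringsAsFactors = FALSE)
}

unclass_note <- function(x) {
  attributes(x) <- NULL
  x
}

# Off-table haplotype: flip one site to an allele combination no star uses.
perturb_haplotype <- function(h, table) {
  keys <- table$hap_keys
  for (attempt in seq_len(50L)) {
    j <- sample.int(length(h), 1L)
    alleles <- table$panel$alleles_observed[[j]]
    alt <- setdiff(alleles, h[[j]])
    if (length(alt) == 0L) next
    cand <- h
    cand[[j]] <- alt[sample.int(length(alt), 1L)]
    if (!(hap_key(cand) %in% keys)) return(cand)
  }
  h
}

#' Mask genotype calls at random
#'
#' Sets each site of each record to missing independently with probability
#' `rate`; reproducible from `seed`.
#'
#' @param records list of [genotype_record] objects.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The masked records.
#' @export
inject_missing <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate >= 1)
    pgx_validation_error("rate must be in [0, 1)")
  if (rate == 0) return(records)
  with_seed(seed, {
    lapply(records, function(r) {
      mask <- stats::runif(length(r$calls)) < rate
      if (!any(mask)) return(r)
      calls <- r$calls
      calls[mask] <- list(NA)
      genotype_record(r$sample_id, calls)
    })
  })
}
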