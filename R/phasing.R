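# Joint statistical haplotype reconstruction across a cohort.
#
# Model: Hardy-Weinberg equilibrium over an unknown haplotype frequency
# vector p. An individual's unordered genotype g is compatible with a set of
# unordered haplotype pairs {h, h'}; under HWE,
#   P({k, l} | p) = c_kl * p_k * p_l,   c_kl = 2 if k != l else 1.
# EM maximizes the observed-data likelihood over p; the E-step posterior
# over an individual's compatible pairs is then its phase posterior.

#' Enumerate the phase resolutions of a genotype record
#'
#' Returns every distinct unordered haplotype pair whose site-wise union of
#' alleles equals the record's genotype at all non-missing sites. Missing
#' sites expand over `wildcards` (the alleles plausible at that variant,
#' typically those seen in the cohort plus the allele definition table).
#' With `h` heterozygous sites and no missing data there are
#' `max(1, 2^(h-1))` resolutions.
#'
#' @param record a [genotype_record].
#' @param wildcards list of per-variant allele sets (panel order) used to
#'   expand missing sites.
#' @param het_cap expansion budget in bits: the sum over sites of
#'   `ceil(log2(number of ordered per-site assignments))` may not exceed
#'   this (a heterozygous site contributes 1 bit, a missing site with `w`
#'   wildcard alleles `ceil(log2(w^2))` bits). Exceeding the cap raises a
#'   resolution-explosion error naming the sample.
#' @return List of resolutions; each is `list(h1, h2)` with `h1 <= h2` in
#'   canonical (byte-lexicographic) order.
#' @export
enumerate_resolutions <- function(record, wildcards, het_cap = 15L) {
  L <- length(record$calls)
  if (length(wildcards) != L)
    pgx_validation_error("wildcards must have one allele set per panel variant")
  opts <- vector("list", L)
  for (j in seq_len(L)) {
    x <- record$calls[[j]]
    if (is_missing_call(x)) {
      w <- sort_radix(unique(as.character(wildcards[[j]])))
      if (length(w) == 0L)
        pgx_validation_error(sprintf(
          "sample %s: no candidate alleles to expand a missing call at variant %d",
          record$sample_id, j))
      opts[[j]] <- as.matrix(expand.grid(a = w, b = w,
                                         KEEP.OUT.ATTRS = FALSE,
                                         stringsAsFactors = FALSE))
    } else if (x[[1L]] == x[[2L]]) {
      opts[[j]] <- matrix(c(x[[1L]], x[[1L]]), nrow = 1L)
    } else {
      opts[[j]] <- matrix(c(x[[1L]], x[[2L]], x[[2L]], x[[1L]]),
                          nrow = 2L, byrow = TRUE)
    }
  }
  n_opts <- vapply(opts, nrow, integer(1))
  bits <- sum(ceiling(log2(pmax(n_opts, 1L))))
  if (bits > het_cap)
    pgx_resolution_error(sprintf(
      "sample %s: %d expansion bits exceed the cap of %d (too many heterozygous/missing sites)",
      record$sample_id, bits, het_cap))

  combos <- expand.grid(lapply(n_opts, seq_len), KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  h1 <- matrix("", nrow = n, ncol = L)
  h2 <- matrix("", nrow = n, ncol = L)
  for (j in seq_len(L)) {
    h1[, j] <- opts[[j]][combos[[j]], 1L]
    h2[, j] <- opts[[j]][combos[[j]], 2L]
  }
  k1 <- apply(h1, 1L, paste, collapse = .HAP_SEP)
  k2 <- apply(h2, 1L, paste, collapse = .HAP_SEP)
  r <- key_ranks(c(k1, k2))
  r1 <- r[seq_len(n)]; r2 <- r[n + seq_len(n)]
  swap <- r1 > r2
  if (any(swap)) {
    tmp <- h1[swap, , drop = FALSE]; h1[swap, ] <- h2[swap, , drop = FALSE]; h2[swap, ] <- tmp
    tk <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tk
  }
  pair_key <- paste(k1, k2, sep = "\x1e")
  keep <- which(!duplicated(pair_key))
  # deterministic output order: sort by (h1, h2)
  ord <- keep[order(k1[keep], k2[keep], method = "radix")]
  lapply(ord, function(i) list(h1 = h1[i, ], h2 = h2[i, ]))
}

#' Estimate haplotype frequencies by EM under Hardy-Weinberg
#'
#' Maximum-likelihood haplotype frequency estimation over the support set
#' (the union of all samples' phase resolutions), jointly across the whole
#' cohort and without an external reference panel. The E-step computes each
#' sample's posterior over its compatible pairs; the M-step re-estimates
#' each haplotype's frequency as its expected share of the `2N` chromosomes.
#' Several restarts guard against multimodality on sparse data: restart 0
#' starts from the uniform distribution, later restarts from seeded
#' Dirichlet draws; the run with the best converged log-likelihood wins.
#'
#' Records with every site missing carry no phase information and are
#' excluded from the likelihood.
#'
#' @param records list of [genotype_record] objects (at least one).
#' @param wildcards per-variant allele sets for missing-site expansion;
#'   `NULL` derives them from the alleles observed in `records`.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of EM restarts.
#' @param seed integer seed for the restart initializations.
#' @param het_cap per-sample expansion cap (see [enumerate_resolutions()]).
#' @return An object of class `hap_freq_set`: haplotype support (character
#'   matrix `haplotypes`), frequency vector `freq` (sums to 1), the
#'   per-iteration `loglik_trace` of the winning restart, `loglik`,
#'   `n_iter`, `converged`, and the restart log-likelihoods.
#' @export
em_estimate <- function(records, wildcards = NULL, tol = 1e-8,
                        max_iter = 1000L, n_restarts = 3L, seed = 1L,
                        het_cap = 15L) {
  if (length(records) == 0L)
    pgx_validation_error("cannot estimate haplotype frequencies from an empty cohort")
  wildcards <- wildcards %||% observed_allele_sets(records)
  pat <- build_patterns(records, wildcards, het_cap)
  if (length(pat$patterns) == 0L)
    pgx_validation_error("every record is fully missing; nothing to estimate")

  K <- nrow(pat$haplotypes)
  N <- sum(vapply(pat$patterns, `[[`, numeric(1), "count"))

  run_em <- function(p0) {
    p <- p0
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      acc <- numeric(K)
      ll <- 0
      for (pt in pat$patterns) {
        w <- pt$c * p[pt$k] * p[pt$l]
        s <- sum(w)
        ll <- ll + pt$count * log(s)
        post <- pt$count * (w / s)
        add <- rowsum(c(post, post), c(pt$k, pt$l))
        idx <- as.integer(rownames(add))
        acc[idx] <- acc[idx] + add[, 1L]
      }
      trace <- c(trace, ll)
      if (it > 1L && abs(ll - trace[[it - 1L]]) < tol) {
        converged <- TRUE
        break
      }
      p <- acc / (2 * N)
    }
    list(p = p, trace = trace, loglik = trace[[length(trace)]], converged = converged)
  }

  inits <- vector("list", n_restarts)
  inits[[1L]] <- rep(1 / K, K)
  if (n_restarts > 1L) {
    for (r in 2:n_restarts) {
      g <- with_seed(seed + r - 1L, stats::rgamma(K, shape = 1))
      inits[[r]] <- g / sum(g)
    }
  }
  runs <- lapply(inits, run_em)
  best <- which.max(vapply(runs, `[[`, numeric(1), "loglik"))
  win <- runs[[best]]

  structure(list(
    haplotypes = pat$haplotypes,
    hap_keys = pat$hap_keys,
    freq = win$p,
    loglik = win$loglik,
    loglik_trace = win$trace,
    n_iter = length(win$trace),
    converged = win$converged,
    restart_logliks = vapply(runs, `[[`, numeric(1), "loglik"),
    n_samples = N,
    wildcards = wildcards
  ), class = "hap_freq_set")
}

#' @export
print.hap_freq_set <- function(x, ...) {
  cat(sprintf("<hap_freq_set> %d haplotype(s), %d sample(s), loglik %.6f (%s in %d iteration(s))\n",
              nrow(x$haplotypes), x$n_samples, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  df <- data.frame(haplotype = apply(x$haplotypes, 1L, paste, collapse = ""),
                   freq = round(x$freq, 6))
  print(df[order(-df$freq), ], row.names = FALSE)
  invisible(x)
}

#' Phase a cohort against estimated haplotype frequencies
#'
#' For each sample, picks the compatible haplotype pair maximizing the
#' Hardy-Weinberg posterior under the estimated frequencies, and reports
#' that posterior. Ties are broken toward the lexicographically smallest
#' pair and flagged `"tie"`. A sample none of whose resolutions has any
#' estimated frequency mass gets a uniform posterior over its resolutions
#' and the flag `"uninformative"`. Fully missing records are returned with
#' `NA` haplotypes and the flag `"all_missing"`.
#'
#' @param records list of [genotype_record] objects (the same cohort the
#'   frequencies were estimated from).
#' @param freqs a `hap_freq_set` from [em_estimate()].
#' @param wildcards per-variant allele sets; defaults to the ones stored in
#'   `freqs` so enumeration matches the EM support.
#' @param het_cap per-sample expansion cap.
#' @return List of `phased_pair` objects: `sample_id`, `h1`, `h2`
#'   (canonical order), `posterior`, `n_resolutions`, `flags`.
#' @export
phase_cohort <- function(records, freqs, wildcards = NULL, het_cap = 15L) {
  stopifnot(inherits(freqs, "hap_freq_set"))
  wildcards <- wildcards %||% freqs$wildcards
  lookup <- stats::setNames(freqs$freq, freqs$hap_keys)
  lapply(records, function(r) {
    if (all(vapply(r$calls, is_missing_call, logical(1))))
      return(structure(list(sample_id = r$sample_id, h1 = NA, h2 = NA,
                            posterior = NA_real_, n_resolutions = 0L,
                            flags = "all_missing"), class = "phased_pair"))
    res <- enumerate_resolutions(r, wildcards, het_cap)
    k1 <- vapply(res, function(p) hap_key(p$h1), character(1))
    k2 <- vapply(res, function(p) hap_key(p$h2), character(1))
    f1 <- unname(lookup[k1]); f1[is.na(f1)] <- 0
    f2 <- unname(lookup[k2]); f2[is.na(f2)] <- 0
    w <- ifelse(k1 == k2, 1, 2) * f1 * f2
    flags <- character(0)
    if (sum(w) == 0) {
      post <- rep(1 / length(res), length(res))
      flags <- c(flags, "uninformative")
    } else {
      post <- w / sum(w)
    }
    top <- max(post)
    tied <- which(post >= top - 1e-9 * max(top, 1e-300))
    if (length(tied) > 1L) flags <- c(flags, "tie")
    # resolutions are emitted in (h1, h2) lexicographic order, so the first
    # tied index is the lexicographically smallest pair
    pick <- tied[[1L]]
    structure(list(sample_id = r$sample_id,
                   h1 = res[[pick]]$h1, h2 = res[[pick]]$h2,
                   posterior = post[[pick]],
                   n_resolutions = length(res),
                   flags = flags), class = "phased_pair")
  })
}

#' @export
print.phased_pair <- function(x, ...) {
  cat(sprintf("<phased_pair> %s: %s | %s (posterior %.4f, %d resolution(s)%s)\n",
              x$sample_id,
              if (is.na(x$h1[[1L]])) "?" else paste(x$h1, collapse = ""),
              if (is.na(x$h2[[1L]])) "?" else paste(x$h2, collapse = ""),
              x$posterior, x$n_resolutions,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

# Per-variant allele sets observed across a cohort's non-missing calls.
observed_allele_sets <- function(records) {
  L <- length(records[[1L]]$calls)
  lapply(seq_len(L), function(j) {
    a <- unlist(lapply(records, function(r) {
      x <- r$calls[[j]]
      if (is_missing_call(x)) character(0) else x
    }), use.names = FALSE)
    sort_radix(unique(a))
  })
}

# Collapse the cohort to unique genotype patterns, enumerate each pattern's
# resolutions once, and index haplotypes into a global support table.
# Fully missing records are dropped (they contribute no likelihood terms).
build_patterns <- function(records, wildcards, het_cap) {
  keep <- !vapply(records, function(r)
    all(vapply(r$calls, is_missing_call, logical(1))), logical(1))
  records <- records[keep]
  if (length(records) == 0L)
    return(list(patterns = list(), haplotypes = NULL, hap_keys = character(0)))
  keys <- vapply(records, genotype_pattern_key, character(1))
  counts <- table(factor(keys, levels = unique(keys)))
  reps <- records[match(names(counts), keys)]
  res_list <- lapply(reps, enumerate_resolutions, wildcards = wildcards,
                     het_cap = het_cap)
  all_k1 <- lapply(res_list, function(res) vapply(res, function(p) hap_key(p$h1), character(1)))
  all_k2 <- lapply(res_list, function(res) vapply(res, function(p) hap_key(p$h2), character(1)))
  support_keys <- sort_radix(unique(c(unlist(all_k1), unlist(all_k2))))
  L <- length(wildcards)
  haplotypes <- do.call(rbind, strsplit(support_keys, .HAP_SEP, fixed = TRUE))
  dim(haplotypes) <- c(length(support_keys), L)
  patterns <- lapply(seq_along(reps), function(i) {
    k <- match(all_k1[[i]], support_keys)
    l <- match(all_k2[[i]], support_keys)
    list(k = k, l = l, c = ifelse(k == l, 1, 2),
         count = as.numeric(counts[[i]]))
  })
  list(patterns = patterns, haplotypes = haplotypes, hap_keys = support_keys)
}
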