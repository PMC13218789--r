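# Independent oracles. These deliberately do not call the package's
# enumeration or EM code paths: resolutions are found by brute force over
# all haplotype pairs, and the maximum-likelihood frequencies by exhaustive
# grid search over the probability simplex.

# All unordered haplotype pairs compatible with a record's genotype:
# enumerate every haplotype over the per-site allele sets and test each
# pair site by site.
oracle_resolutions <- function(record, wildcards) {
  calls <- record$calls
  site_sets <- lapply(seq_along(calls), function(j) {
    x <- calls[[j]]
    if (length(x) == 1L && is.na(x)) wildcards[[j]] else unique(x)
  })
  haps <- expand.grid(site_sets, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(haps)
  pairs <- list()
  for (i in seq_len(n)) for (k in i:n) {
    ok <- TRUE
    for (j in seq_along(calls)) {
      x <- calls[[j]]
      if (length(x) == 1L && is.na(x)) next
      u <- sort(c(haps[i, j], haps[k, j]), method = "radix")
      if (!identical(u, as.character(x))) { ok <- FALSE; break }
    }
    if (ok) {
      h1 <- as.character(haps[i, ]); h2 <- as.character(haps[k, ])
      if (hap_key_of(h2) < hap_key_of(h1)) { tmp <- h1; h1 <- h2; h2 <- tmp }
      pairs[[length(pairs) + 1L]] <- list(h1 = h1, h2 = h2)
    }
  }
  pairs
}

# Log-likelihood of a frequency matrix P (rows = candidate frequency
# vectors over `support_keys`) for a cohort, under Hardy-Weinberg.
oracle_loglik <- function(P, patterns) {
  ll <- numeric(nrow(P))
  for (pt in patterns) {
    term <- numeric(nrow(P))
    for (t in seq_along(pt$k)) {
      term <- term + pt$c[[t]] * P[, pt$k[[t]]] * P[, pt$l[[t]]]
    }
    ll <- ll + pt$count * log(term)
  }
  ll
}

# Cohort -> (support keys, per-pattern resolution index lists), via the
# brute-force enumerator.
oracle_patterns <- function(records, wildcards) {
  res <- lapply(records, oracle_resolutions, wildcards = wildcards)
  k1 <- lapply(res, function(r) vapply(r, function(p) hap_key_of(p$h1), character(1)))
  k2 <- lapply(res, function(r) vapply(r, function(p) hap_key_of(p$h2), character(1)))
  support <- sort(unique(c(unlist(k1), unlist(k2))), method = "radix")
  patterns <- lapply(seq_along(records), function(i) {
    k <- match(k1[[i]], support); l <- match(k2[[i]], support)
    list(k = k, l = l, c = ifelse(k == l, 1, 2), count = 1)
  })
  list(support = support, patterns = patterns)
}

# All compositions of m into K non-negative parts (rows), m small.
compositions <- function(K, m) {
  if (K == 1L) return(matrix(m, 1L, 1L))
  g <- as.matrix(expand.grid(rep(list(0:m), K - 1L)))
  g <- g[rowSums(g) <= m, , drop = FALSE]
  unname(cbind(g, m - rowSums(g)))
}

# Exhaustive grid search for the ML haplotype frequencies at 1e-3 simplex
# resolution: a full coarse grid (step 1/100) over the whole simplex, then
# the full 1e-3-step grid inside a box around the coarse optimum.
oracle_grid_search <- function(records, wildcards, box_steps = 20L) {
  op <- oracle_patterns(records, wildcards)
  K <- length(op$support)
  coarse <- compositions(K, 100L) / 100
  ll <- oracle_loglik(coarse, op$patterns)
  best <- coarse[which.max(ll), ]

  c0 <- round(best * 1000)
  offs <- expand.grid(rep(list(-box_steps:box_steps), K - 1L))
  cand <- matrix(rep(c0[-K], each = nrow(offs)), ncol = K - 1L) + as.matrix(offs)
  lastcol <- 1000 - rowSums(cand)
  cand <- cbind(cand, lastcol)
  keep <- apply(cand >= 0, 1L, all)
  cand <- cand[keep, , drop = FALSE] / 1000
  llf <- oracle_loglik(cand, op$patterns)
  i <- which.max(llf)
  list(freq = stats::setNames(cand[i, ], op$support),
       loglik = llf[[i]],
       support = op$support)
}
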