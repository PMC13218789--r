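wild2 <- list(c("C", "T"), c("A", "G"))

test_that("resolution enumeration matches its definition on het and missing sites", {
  r_hom <- make_records("C/C,A/G")[[1]]
  res <- enumerate_resolutions(r_hom, wild2)
  expect_length(res, 1L)
  expect_identical(res[[1]]$h1, c("C", "A"))
  expect_identical(res[[1]]$h2, c("C", "G"))

  r_het2 <- make_records("C/T,A/G")[[1]]
  res2 <- enumerate_resolutions(r_het2, wild2)
  expect_length(res2, 2L)  # 2^(2-1)
  got <- lapply(res2, function(p) paste(c(p$h1, p$h2), collapse = ""))
  expect_setequal(unlist(got), c("CATG", "CGTA"))

  r_miss <- make_records("?,G/G")[[1]]
  res3 <- enumerate_resolutions(r_miss, wild2)
  expect_length(res3, 3L)  # {CG,CG}, {CG,TG}, {TG,TG}
})

test_that("enumeration agrees with the brute-force oracle on random records", {
  wild3 <- list(c("A", "C"), c("G", "T"), c("A", "G", "T"))
  set.seed(5)
  for (i in 1:50) {
    calls <- lapply(wild3, function(w) {
      if (runif(1) < 0.2) NA else sort(sample(w, 2, replace = TRUE), method = "radix")
    })
    rec <- genotype_record("R", calls)
    got <- enumerate_resolutions(rec, wild3)
    want <- oracle_resolutions(rec, wild3)
    key <- function(p) paste(hap_key_of(p$h1), hap_key_of(p$h2), sep = "#")
    expect_setequal(vapply(got, key, character(1)), vapply(want, key, character(1)))
  }
})

test_that("with h het sites and no missing data there are max(1, 2^(h-1)) resolutions", {
  wild <- rep(list(c("A", "B")), 6)
  for (h in 0:6) {
    calls <- c(rep(list(c("A", "B")), h), rep(list(c("A", "A")), 6 - h))
    rec <- genotype_record("R", calls)
    expect_length(enumerate_resolutions(rec, wild), max(1L, 2L^(h - 1L)))
  }
})

test_that("the het/missing expansion cap triggers a resolution-explosion error", {
  wild <- rep(list(c("A", "B")), 20)
  rec <- genotype_record("BIG", rep(list(c("A", "B")), 20))
  expect_error(enumerate_resolutions(rec, wild, het_cap = 15),
               "BIG", class = "pgx_resolution_error")
  expect_silent(enumerate_resolutions(genotype_record("OK", rep(list(c("A", "B")), 15)),
                                      rep(list(c("A", "B")), 15), het_cap = 15))
})

test_that("EM on an unambiguous cohort is the exact chromosome-count fixed point", {
  recs <- make_records(c("C/C,G/G", "C/C,G/G", "T/T,A/A", "C/C,A/A"))
  fit <- em_estimate(recs, wild2)
  # 8 chromosomes: CG x4, TA x2, CA x2
  want <- c(CA = 0.25, CG = 0.5, TA = 0.25)
  got <- stats::setNames(fit$freq, apply(fit$haplotypes, 1, paste, collapse = ""))
  expect_equal(got[names(want)], want, tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("EM attains the grid-search maximum on the three-sample toy cohort", {
  recs <- make_records(c("C/T,G/G", "C/C,G/A", "C/T,G/A"))
  fit <- em_estimate(recs, wild2, tol = 1e-10)
  oracle <- oracle_grid_search(recs, wild2)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  got <- stats::setNames(fit$freq, fit$hap_keys)
  expect_true(all(abs(got[oracle$support] - oracle$freq) <= 1e-3))
})

test_that("a lone double heterozygote has two symmetric optima of equal likelihood", {
  recs <- make_records("C/T,G/A")
  fit <- em_estimate(recs, wild2, n_restarts = 3, seed = 7)
  # the two perturbed restarts fall into the two symmetric optima, whose
  # log-likelihoods are equal; the uniform start sits on the symmetric
  # saddle, so the best-restart rule is what rescues the fit
  perturbed <- fit$restart_logliks[-1]
  expect_lt(diff(range(perturbed)), 1e-9)
  expect_equal(fit$loglik, max(fit$restart_logliks))
  expect_equal(fit$loglik, log(0.5), tolerance = 1e-6)
})

test_that("the log-likelihood trace is non-decreasing and frequencies form a distribution", {
  tab <- toy_allele_table()
  for (s in 1:20) {
    sim <- generate_cohort(simulation_config(toy_freqs, 25, missing_rate = 0.05,
                                             seed = s), tab)
    fit <- em_estimate(sim$records, n_restarts = 2, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(sum(fit$freq), 1, tolerance = 1e-9)
    expect_true(all(fit$freq >= 0))
  }
})

test_that("sample order does not affect frequencies or phase calls", {
  tab <- toy_allele_table()
  sim <- generate_cohort(simulation_config(toy_freqs, 40, missing_rate = 0.05,
                                           seed = 9), tab)
  fit1 <- em_estimate(sim$records, seed = 1)
  perm <- { set.seed(123); sample(seq_along(sim$records)) }
  fit2 <- em_estimate(sim$records[perm], seed = 1)
  f1 <- stats::setNames(fit1$freq, fit1$hap_keys)
  f2 <- stats::setNames(fit2$freq, fit2$hap_keys)
  expect_identical(names(f1), names(f2))
  expect_true(all(abs(f1 - f2) <= 1e-9))

  ph1 <- phase_cohort(sim$records, fit1)
  ph2 <- phase_cohort(sim$records[perm], fit2)
  ids1 <- vapply(ph1, `[[`, character(1), "sample_id")
  ids2 <- vapply(ph2, `[[`, character(1), "sample_id")
  dip <- function(p) paste(hap_key_of(p$h1), hap_key_of(p$h2), sep = "#")
  expect_identical(vapply(ph1, dip, character(1)),
                   vapply(ph2, dip, character(1))[match(ids1, ids2)])
})

test_that("phase posteriors: certainty, ties, and uninformative samples", {
  # <=1 het site, no missing -> single resolution, posterior exactly 1
  recs <- make_records(c("C/C,G/G", "C/T,G/G"))
  fit <- em_estimate(recs, wild2)
  ph <- phase_cohort(recs, fit)
  expect_identical(vapply(ph, `[[`, numeric(1), "posterior"), c(1, 1))
  expect_identical(vapply(ph, `[[`, integer(1), "n_resolutions"), c(1L, 1L))

  # exactly equal weights -> lexicographically smallest pair, tie flag
  keys <- c(hap_key_of(c("C", "A")), hap_key_of(c("C", "G")),
            hap_key_of(c("T", "A")), hap_key_of(c("T", "G")))
  uni <- fixed_freq_set(stats::setNames(rep(0.25, 4), keys), wild2)
  tied <- phase_cohort(make_records("C/T,A/G"), uni)[[1]]
  expect_true("tie" %in% tied$flags)
  expect_identical(tied$h1, c("C", "A"))  # smallest pair leads
  expect_identical(tied$h2, c("T", "G"))
  expect_equal(tied$posterior, 0.5)

  # no frequency mass on any resolution -> uniform posterior, flagged
  only_cg <- fixed_freq_set(stats::setNames(1, hap_key_of(c("C", "G"))), wild2)
  uninf <- phase_cohort(make_records("T/T,A/A"), only_cg)[[1]]
  expect_true("uninformative" %in% uninf$flags)
  expect_equal(uninf$posterior, 1)

  # fully missing record is flagged, not phased
  blank <- phase_cohort(make_records("?,?"), only_cg)[[1]]
  expect_true("all_missing" %in% blank$flags)
  expect_true(is.na(blank$posterior))
})

test_that("estimated frequencies approach simulation truth as the cohort grows", {
  tab <- toy_allele_table()
  truth <- star_freqs_to_hap_freqs(toy_freqs, tab)
  mae <- function(n, seed) {
    sim <- generate_cohort(simulation_config(toy_freqs, n, seed = seed), tab)
    fit <- em_estimate(sim$records, seed = 1)
    est <- stats::setNames(fit$freq, fit$hap_keys)
    full <- stats::setNames(rep(0, length(truth)), names(truth))
    common <- intersect(names(est), names(full))
    full[common] <- est[common]
    mean(abs(full - truth))
  }
  expect_lt(mae(2000, seed = 101), mae(100, seed = 101))
})

test_that("an empty cohort is rejected", {
  expect_error(em_estimate(list()), "empty cohort", class = "pgx_validation_error")
})
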