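tab3 <- toy_allele_table()

mk_pair <- function(h1, h2) {
  p <- list(sample_id = "S", h1 = h1, h2 = h2, posterior = 1,
            n_resolutions = 1L, flags = character(0))
  class(p) <- "phased_pair"
  p
}

call_for <- function(star1, star2) {
  idx <- match(c(star1, star2), tab3$stars$star)
  pair <- mk_pair(tab3$haplotypes[idx[[1]], ], tab3$haplotypes[idx[[2]], ])
  list(pair = pair, matches = call_diplotype(pair, tab3))
}

test_that("copy-number rules: default, deletion, homozygous deletion, duplication", {
  # cnv = 2 leaves the call unchanged
  x <- call_for("*1", "*4")
  adj <- apply_cnv(x$matches, x$pair, 2L)
  expect_identical(adj$diplotype, "*1/*4")
  expect_identical(adj$kind, "normal")
  expect_length(adj$flags, 0L)

  # cnv = 1 with an apparently homozygous genotype: second allele becomes *5
  hom <- call_for("*4", "*4")
  del <- apply_cnv(hom$matches, hom$pair, 1L)
  expect_identical(del$diplotype, "*4/*5")
  expect_identical(del$kind, "deletion")

  # cnv = 1 with a heterozygous genotype: kept, flagged as a CNV conflict
  conflict <- apply_cnv(x$matches, x$pair, 1L)
  expect_identical(conflict$diplotype, "*1/*4")
  expect_true("hemizygosity_conflict" %in% conflict$flags)

  # cnv = 0: homozygous deletion, flagged as an extrapolation
  zero <- apply_cnv(x$matches, x$pair, 0L)
  expect_identical(zero$diplotype, "*5/*5")
  expect_true("homozygous_deletion_assumed" %in% zero$flags)

  # cnv = 3, identical alleles: duplicated allele inferred
  dup <- call_for("*1", "*1")
  d3 <- apply_cnv(dup$matches, dup$pair, 3L)
  expect_identical(d3$diplotype, "*1x2/*1")
  expect_identical(d3$kind, "duplication")

  # cnv = 3, different alleles: indeterminate
  ind <- apply_cnv(x$matches, x$pair, 3L)
  expect_identical(ind$kind, "indeterminate_dup")
  expect_true("indeterminate_duplication" %in% ind$flags)
})

test_that("activity scores sum activities, score deletions at zero, scale duplications", {
  x <- call_for("*1", "*4")
  expect_equal(activity_score(apply_cnv(x$matches, x$pair, 2L))$value, 1.0)

  hom4 <- call_for("*4", "*4")
  expect_equal(activity_score(apply_cnv(hom4$matches, hom4$pair, 1L))$value, 0)

  # deletion law: AS(h, *5) = act(h) for every star in the table
  for (s in tab3$stars$star) {
    hs <- call_for(s, s)
    as_del <- activity_score(apply_cnv(hs$matches, hs$pair, 1L))
    expect_equal(as_del$value, tab3$stars$activity[[match(s, tab3$stars$star)]])
  }

  # homozygous-duplication law: AS = n * act(A) for n in 3..5
  for (n in 3:5) {
    d <- call_for("*41", "*41")
    expect_equal(activity_score(apply_cnv(d$matches, d$pair, n))$value, n * 0.5)
  }
  d1 <- call_for("*1", "*1")
  expect_equal(activity_score(apply_cnv(d1$matches, d1$pair, 3L))$value, 3.0)

  # heterozygous duplication: indeterminate with dosage bounds
  ind <- activity_score(apply_cnv(x$matches, x$pair, 3L))
  expect_true(ind$indeterminate)
  expect_equal(ind$bounds, c(1.0, 2.0))  # 1 + 0 + 1*{0, 1}

  # AS is symmetric in the two alleles
  y <- call_for("*4", "*1")
  expect_equal(activity_score(apply_cnv(y$matches, y$pair, 2L))$value, 1.0)
})

test_that("phenotype classification is an interval lookup with PM fixed at AS = 0", {
  thr <- default_thresholds()
  expect_identical(classify_phenotype(0, thr), "PM")
  expect_identical(classify_phenotype(0.25, thr), "IM")
  expect_identical(classify_phenotype(1.0, thr), "IM")
  expect_identical(classify_phenotype(1.25, thr), "NM")
  expect_identical(classify_phenotype(2.25, thr), "NM")
  expect_identical(classify_phenotype(2.5, thr), "UM")
  expect_identical(classify_phenotype(3.0, thr), "UM")
})

test_that("classification is monotone in the activity score", {
  thr <- default_thresholds()
  grid <- seq(0, 4, by = 0.05)
  cats <- vapply(grid, classify_phenotype, character(1), thresholds = thr)
  ranks <- match(cats, c("PM", "IM", "NM", "UM"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("indeterminate AS classifies by bounds subsumption", {
  thr <- default_thresholds()
  inside_im <- new_as_for_test(c(0.25, 0.5))
  expect_identical(unclass_attr(classify_phenotype(inside_im, thr)), "IM")
  expect_match(attr(classify_phenotype(inside_im, thr), "note"), "IM")

  spanning <- new_as_for_test(c(1.0, 2.0))
  expect_identical(classify_phenotype(spanning, thr), "Indeterminate")

  above_um <- new_as_for_test(c(2.5, 3.5))
  expect_identical(unclass_attr(classify_phenotype(above_um, thr)), "UM")
})

test_that("malformed thresholds fail at load time", {
  bad_gap <- data.frame(category = c("PM", "IM", "NM", "UM"),
                        lower = c(0, 0, 1.5, 2.25),
                        upper = c(0, 1.25, 2.25, Inf),
                        lower_open = c(FALSE, TRUE, FALSE, TRUE),
                        upper_open = c(FALSE, TRUE, FALSE, TRUE))
  expect_error(validate_thresholds(bad_gap), "tile", class = "pgx_config_error")

  no_pm_zero <- data.frame(category = c("PM", "IM"),
                           lower = c(0.5, 1), upper = c(1, Inf),
                           lower_open = c(FALSE, TRUE),
                           upper_open = c(TRUE, TRUE))
  expect_error(validate_thresholds(no_pm_zero), class = "pgx_config_error")

  finite_top <- data.frame(category = c("PM", "IM"),
                           lower = c(0, 0), upper = c(0, 4),
                           lower_open = c(FALSE, TRUE),
                           upper_open = c(FALSE, FALSE))
  expect_error(validate_thresholds(finite_top), "infinity", class = "pgx_config_error")
})

test_that("threshold config files round-trip through the CSV reader", {
  thr <- default_thresholds()
  path <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(thr), path, row.names = FALSE)
  thr2 <- read_thresholds(path)
  expect_equal(as.data.frame(thr2), as.data.frame(thr))
  # custom partition: merge NM and UM
  custom <- data.frame(category = c("PM", "IM", "NM"),
                       lower = c(0, 0, 1.25), upper = c(0, 1.25, Inf),
                       lower_open = c(FALSE, TRUE, FALSE),
                       upper_open = c(FALSE, TRUE, TRUE))
  utils::write.csv(custom, path, row.names = FALSE)
  thr3 <- read_thresholds(path)
  expect_identical(classify_phenotype(3.5, thr3), "NM")
})
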