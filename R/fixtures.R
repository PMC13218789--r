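# Built-in demonstration allele tables. These are code-built fixtures: a
# tiny 3-variant table for examples and unit tests, and a 12-variant,
# 13-star CYP2D6-like table (plus *5, the whole-gene deletion, which enters
# through the copy-number path rather than a haplotype vector) for
# cohort-scale runs. The defining vectors are synthetic but follow the
# real CYP2D6 variant nomenclature and CPIC-style activity values.

#' Tiny 3-variant demonstration allele table
#'
#' Panel `v1, v2, v3`; stars *1 (Normal, 1.0), *4 (No function, 0.0),
#' *10 (Decreased, 0.25), *41 (Decreased, 0.5).
#'
#' @return An [allele_table].
#' @export
toy_allele_table <- function() {
  panel <- variant_panel(c("v1", "v2", "v3"),
                         list(c("C", "T"), c("A", "G"), c("A", "G")))
  allele_table(
    star = c("*1", "*4", "*10", "*41"),
    fn = c("Normal", "No function", "Decreased", "Decreased"),
    activity = c(1.0, 0.0, 0.25, 0.5),
    haplotypes = rbind(
      c("C", "G", "G"),   # *1
      c("C", "A", "G"),   # *4
      c("T", "G", "G"),   # *10
      c("C", "G", "A")),  # *41
    panel = panel)
}

#' Twelve-variant CYP2D6-like demonstration allele table
#'
#' A synthetic stand-in for a targeted 12-variant CYP2D6 panel resolving
#' the common alleles *1, *2, *3, *4, *6, *9, *10, *17, *29, *34, *35,
#' *39 and *41; together with *5 (whole-gene deletion, called from the
#' copy-number table) this covers 14 star alleles. Variant labels use
#' CYP2D6 nucleotide-change nomenclature and the defining variant
#' combinations mirror the published definitions at panel resolution;
#' activity values follow the CPIC scheme (Normal 1.0, Decreased
#' 0.25-0.5, No function 0).
#'
#' @return An [allele_table].
#' @export
cyp2d6_demo_alleles <- function() {
  variants <- c("31G>A", "100C>T", "1023C>T", "1659G>A", "1707delT",
                "1846G>A", "2549delA", "2615_2617delAAG", "2850C>T",
                "2988G>A", "3183G>A", "4180G>C")
  ref <- c("G", "C", "C", "G", "T", "G", "A", "AAG", "C", "G", "G", "G")
  alt <- c("A", "T", "T", "A", "del", "A", "del", "del", "T", "A", "A", "C")
  defs <- list(
    "*1"  = list(integer(0),           "Normal",      1.0),
    "*2"  = list(c(9L, 12L),           "Normal",      1.0),
    "*3"  = list(7L,                   "No function", 0.0),
    "*4"  = list(c(2L, 6L, 12L),       "No function", 0.0),
    "*6"  = list(5L,                   "No function", 0.0),
    "*9"  = list(8L,                   "Decreased",   0.5),
    "*10" = list(c(2L, 12L),           "Decreased",   0.25),
    "*17" = list(c(3L, 9L, 12L),       "Decreased",   0.5),
    "*29" = list(c(4L, 9L, 11L, 12L),  "Decreased",   0.5),
    "*34" = list(9L,                   "Normal",      1.0),
    "*35" = list(c(1L, 9L, 12L),       "Normal",      1.0),
    "*39" = list(12L,                  "Normal",      1.0),
    "*41" = list(c(9L, 10L, 12L),      "Decreased",   0.5)
  )
  haps <- t(vapply(defs, function(d) {
    h <- ref
    h[d[[1L]]] <- alt[d[[1L]]]
    h
  }, character(length(variants))))
  panel <- variant_panel(variants, lapply(seq_along(ref), function(j) c(ref[[j]], alt[[j]])))
  allele_table(
    star = names(defs),
    fn = vapply(defs, `[[`, character(1), 2L),
    activity = vapply(defs, `[[`, numeric(1), 3L),
    haplotypes = haps,
    panel = panel)
}

#' Star-allele frequencies for the 12-variant demonstration table
#'
#' A realistic frequency vector for an admixed, malaria-endemic population
#' (high *1/*2, appreciable *4, *17, *29, *41): the cohort model used by
#' the simulator's examples and the package's own benchmark runs.
#'
#' @return Named numeric vector over the stars of
#'   [cyp2d6_demo_alleles()], summing to 1.
#' @export
cyp2d6_demo_frequencies <- function() {
  c("*1" = 0.32, "*2" = 0.20, "*3" = 0.01, "*4" = 0.11, "*6" = 0.01,
    "*9" = 0.02, "*10" = 0.06, "*17" = 0.10, "*29" = 0.06, "*34" = 0.01,
    "*35" = 0.02, "*39" = 0.02, "*41" = 0.06)
}
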