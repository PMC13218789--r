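Package: pgxphaser
Title: CYP2D6 Star-Allele Diplotyping from Targeted Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts unphased targeted-assay CYP2D6 genotype tables into
    star-allele diplotypes, activity scores, and metabolizer phenotypes.
    Haplotypes are reconstructed jointly across the cohort by
    maximum-likelihood haplotype-frequency estimation under Hardy-Weinberg
    equilibrium (an EM algorithm with per-individual phase posteriors), then
    matched exactly against a user-supplied star-allele definition table.
    Copy-number information adjusts the called diplotype (gene deletion to
    *5, duplication scoring, indeterminate heterozygous duplications) before
    CPIC-style activity-score thresholds assign the metabolizer phenotype.
    Includes readers and writers for the genotype, allele-definition,
    copy-number and report CSV dialects and for the classic PHASE text
    interchange format, a synthetic-cohort simulator with known truth, and a
    command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
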