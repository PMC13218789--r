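---
title: "Statistical star-allele diplotyping: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical star-allele diplotyping: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxphaser)
```

## The problem

Targeted CYP2D6 assays report, for each sample and each panel variant, an
*unordered* pair of alleles. Star-allele calling, however, is defined on
haplotypes: a star allele is a named combination of variants on one
chromosome copy. pgxphaser bridges that gap in three stages — statistical
phasing, exact haplotype matching, copy-number-aware scoring — and this
vignette documents the model behind each stage, the tunable parameters,
and the design decisions taken where more than one defensible choice
existed.

## Phasing model

Let the panel have $L$ variants and let $p = (p_1, \dots, p_K)$ be the
unknown frequencies of the haplotypes in the *support set* — the union,
over all samples, of every haplotype appearing in some resolution of that
sample's genotype. Under Hardy–Weinberg equilibrium a sample with genotype
$g$ compatible with the unordered pair $\{h_k, h_l\}$ has

$$P(\{k,l\} \mid p) = c_{kl}\, p_k\, p_l, \qquad
  c_{kl} = \begin{cases} 2 & k \neq l \\ 1 & k = l \end{cases}$$

and the observed-data likelihood is the product over samples of the sum
over compatible pairs. `em_estimate()` maximizes this by EM:

* **E-step** — for sample $i$,
  $P(\{k,l\} \mid g_i, p) = c_{kl} p_k p_l \big/ \sum_{\{k',l'\}} c_{k'l'} p_{k'} p_{l'}$
  over the pairs compatible with $g_i$;
* **M-step** — $p_k = \frac{1}{2N} \sum_i \sum_{\{k',l'\} \ni k} m_k\,
  P(\{k',l'\} \mid g_i, p)$, where $m_k$ is the multiplicity of $k$ in the
  pair (2 for homozygotes).

The log-likelihood trace is recorded and is non-decreasing by the standard
EM argument; the test suite asserts this across randomized cohorts. A
sample with $h$ heterozygous sites and no missing data has
$\max(1, 2^{h-1})$ resolutions; missing sites expand over the alleles seen
at that variant in the cohort and in the allele definition table (the
semantics of PHASE's `?` token), not by imputation to a reference allele.

Phasing is *joint across the cohort and reference-free*: the frequencies
come from the data being phased. This is also the method's main
limitation — with few samples, rare haplotypes, or weak linkage
information the posterior flattens, and single-sample runs are possible
but uninformative (the pipeline warns). Per-individual phase posteriors
are always reported so downstream users can threshold them; the package
deliberately reports the single best pair plus its posterior rather than
posterior samples.

### Relation to PHASE

The classic workflow for this problem shells out to the PHASE 2.1.1
binary, whose model adds an approximate-coalescent prior over haplotypes.
pgxphaser implements phasing natively — maximum likelihood under
Hardy–Weinberg with EM — because a portable R package cannot reasonably
script an unmaintained interactive binary, and at targeted-panel scale
(a dozen variants, hundreds of samples) the likelihood term dominates the
prior. The coalescent prior is explicitly *not* reproduced. To preserve
the original architecture, `write_phase_input()` and
`read_phase_output()` implement the PHASE text dialect, so users who
prefer PHASE's model can export the cohort, run the binary themselves,
and re-import its best pairs in place of `phase_cohort()` output.

### Numerical choices

| Parameter | Default | Why |
|---|---|---|
| convergence tolerance `tol` | 1e-8 on the log-likelihood change | conventional; iterations are cheap at panel scale |
| `max_iter` | 1000 | safety cap, rarely reached |
| `n_restarts` | 3 | restart 0 is the uniform distribution; restarts 1–2 are seeded Dirichlet(1) draws. The HWE likelihood can be multimodal on sparse data, and perfectly symmetric genotypes make the uniform start a saddle point — the perturbed restarts break that symmetry, and the best converged log-likelihood wins |
| `het_cap` | 15 expansion bits | a per-sample budget on $\sum_j \lceil \log_2(\text{ordered options at site } j) \rceil$: a heterozygous site costs 1 bit, a missing biallelic site 2. Twelve-variant panels sit far below the cap; exceeding it raises a named error rather than exhausting memory |
| `seed` | 1 | controls the Dirichlet restarts (and, in the simulator, everything); identical inputs and seed give byte-identical reports |

Determinism details worth stating: haplotypes are ordered by a
locale-independent byte-wise (radix) sort everywhere, pairs are stored
with $h_1 \le h_2$, exact posterior ties are broken toward the
lexicographically smallest pair and flagged `tie`, and a sample none of
whose resolutions retains frequency mass receives a uniform posterior and
the flag `uninformative`. Identical genotype patterns are collapsed
before EM, so cohort cost scales with the number of *distinct* genotypes,
and shuffling sample order cannot change any estimate.

## Star-allele matching

`match_haplotype()` is exact, site-wise equality against every definition
row, with two deliberate policies:

* **No-call over default.** A haplotype matching no row is reported as
  `*?` with a sample-level `no_call` flag and an indeterminate activity
  score. Defaulting to `*1` (as a "reference" fallback) would fabricate a
  normal-function call out of an assay gap; exact matching keeps the error
  visible.
* **Ambiguity groups.** Definition rows with identical allele vectors are
  indistinguishable on the panel; they load with a warning and match as a
  joined label (`*2|*35`). The group's activity value is used only when
  all members agree; otherwise the sample's score is indeterminate. This
  is the conservative reading of an under-determined panel.

Diplotype strings are rendered with calls sorted by star number
(`*1/*4`, `*10/*41`), and `parse_diplotype()` inverts the rendering.

## Copy-number rules and scoring

Two copies are assumed for every sample absent from the CNV table. The
rules, with `act()` the activity value and `*5` the deleted gene (activity
0 by definition of absence):

| CNV | genotype | result | AS |
|---|---|---|---|
| 2 | any | unchanged | `act(A) + act(B)` |
| 1 | apparently homozygous `A/A` | `A/*5` | `act(A)` |
| 1 | heterozygous | kept, flagged `hemizygosity_conflict` | `act(A) + act(B)` |
| 0 | (calls all missing) | `*5/*5`, flagged | 0 |
| n ≥ 3 | identical calls `A/A` | `Ax(n-1)/A` | `n · act(A)` |
| n ≥ 3 | different calls | indeterminate | bounds `[act(A)+act(B)+(n-2)·min, … ·max]` |

A single reported copy with a heterozygous genotype contradicts the assay
(one chromosome cannot carry two alleles); it is flagged rather than
fatal because the more likely culprit is the CNV estimate, and the user
should decide. Zero copies extrapolate beyond the deletion rule (which
the source workflow defines only down to one copy); the call is `*5/*5`
with an explicit flag. The dosage bounds on indeterminate duplications
are an optional refinement beyond the bare "indeterminate": when both
bounds land in one phenotype category the category is reported with a
`phenotype_from_bounds` note, since the phenotype is then known even
though the exact score is not.

Phenotype classification is interval lookup in a validated partition of
$[0, \infty)$. The defaults are the CPIC activity-score consensus —
PM $= \{0\}$, IM $= (0, 1.25)$, NM $= [1.25, 2.25]$, UM $= (2.25, \infty)$ —
held as configuration (overridable via `read_thresholds()`), never as
constants inside the classifier; malformed partitions (gaps, overlaps, a
finite last interval, PM not containing 0) fail at load time.

## The simulator: what it emulates and what it does not

`generate_cohort()` draws two star alleles per sample i.i.d. from a
frequency vector (Hardy–Weinberg pairing), materializes their haplotype
vectors from the definition table, collapses them to unordered calls,
optionally masks sites i.i.d. (`missing_rate`), and draws copy numbers
from `cnv_spec`. Truth labels are computed through the same CNV and
scoring rules the pipeline applies, so "truth" means *what an oracle with
phased data and the same rules would report*. Everything is reproducible
from the config seed.

The built-in `cyp2d6_demo_alleles()` table (12 variants, 13
haplotype-defined stars; *5 arrives via CNV, for 14 callable alleles) and
`cyp2d6_demo_frequencies()` (high *1/*2, appreciable *4, *17, *29, *41 —
the profile of an admixed malaria-endemic population, chosen once when the
fixture was built) define the package's standard validation conditions.
The simulator deliberately matches the phaser's model: it draws under HWE
from table rows only. Passing recovery tests therefore demonstrates
correct inference *under the model*, not robustness to population
structure, assay genotyping error, de-novo haplotypes (available
separately via `novel_rate`), CYP2D7 hybrids or gene conversions — none
of which the simulator emulates. Real-data performance depends on how far
a cohort departs from these assumptions.

## Validation problem sizes

The shipped tests exercise: exhaustive-enumeration and grid-search
oracles on 2–3-variant toys (the grid oracle reaches 1e-3 simplex
resolution via a coarse 1e-2 pass plus an exhaustive 1e-3 refinement box,
and EM must reach its optimum within 1e-6 log-likelihood and 1e-3 per
frequency); EM monotonicity over 100 randomized cohorts; end-to-end truth
recovery on a 500-sample, 12-variant cohort (diplotype concordance ≥ 95%,
phenotype ≥ 97% under the standard conditions above); and a 1300-sample
batch for scale and byte-stability. These sizes were chosen as the
smallest that make the statistical claims meaningful: concordance rates
stabilize well below n = 500, and 1300 matches the batch size the package
targets for routine cohort use.

## Known limitations

* The phaser has no recombination or coalescent model; it is intended for
  a single short gene region, not long-range phasing.
* Accuracy degrades on small or uninformative cohorts — inspect the phase
  posteriors, or substitute PHASE output via the dialect readers.
* Star alleles defined by structural events other than whole-gene
  deletion/duplication (hybrids, conversions) are out of scope.
* Genotype input must be a targeted-assay table; VCF/sequencing input is
  not parsed.
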