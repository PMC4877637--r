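---
title: "Methods: screening for promoter-hypermethylated silenced lncRNA genes"
author: "episcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for promoter-hypermethylated silenced lncRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The screening model

Epigenetic silencing of a gene by promoter CpG-island (CGI) hypermethylation
leaves a characteristic multi-layer signature: the promoter loses the active
mark H3K4me3 in the tumor cell, regains it when DNA methylation is removed
(genetically, by knocking out the maintenance and de novo DNA
methyltransferases, or pharmacologically, with a demethylating nucleoside
analogue), carries dense methylation over a promoter CGI in tumor but not in
normal tissue, and shows expression that is present in normal tissue,
reduced in the tumor line, and restored by demethylation. `episcreen`
operationalizes this signature as an ordered funnel of per-transcript
predicates over a TSS annotation:

1. **H3K4me3 universe** — a TSS is H3K4me3-positive in a cell line when at
   least one ChIP-seq peak overlaps the window ±2 kb around the TSS by one
   or more bases. Broad marks (H3K27me3, H3K79me2) use ±5 kb windows.
   Overlap is evaluated under half-open interval semantics; a single shared
   base suffices, because the positivity definition is pure overlap with no
   minimum fraction.
2. **H3K4me3 gain** — comparison of the parent tumor line with its
   demethylated derivative. Two interpretations of an "upregulated" mark
   are supported: `binary` (absent in parent, present in derivative) and
   `quantitative` (present in derivative and either absent in parent or
   with a pseudocounted signal ratio `(derivative + 1)/(parent + 1)` of at
   least `minRatio`, default 2). The quantitative mode is the default
   because acquisition and increase are both biologically meaningful
   reactivation signals; with `minRatio = Inf` it degenerates exactly to
   the binary mode, which the test suite asserts.
3. **RRBS availability** — promoter methylation is the unweighted mean of
   per-CpG levels (methylated/total reads) over CpGs inside ±500 bp of the
   TSS with at least `minDepth = 10` reads; a promoter with fewer than
   `minCpgs = 3` surviving CpGs is *unavailable*, mirroring the incomplete
   promoter coverage of reduced-representation bisulfite sequencing. A
   read-weighted mean is available as an option; the unweighted mean is the
   default because region-level RRBS percentages are conventionally simple
   averages of site percentages.
4. **Cancer-specific methylation** — tumor promoter methylation strictly
   above 60% and every available normal tissue strictly below 40%
   (strictness follows the printed ">"/"<" conventions; an "any normal"
   mode exists for sensitivity analysis). Methylation levels are also
   stratified into the five bins 0–20, 20–40, 40–60, 60–80, 80–100%.
   Whether bin edges are lower- or upper-inclusive is a convention the
   source material leaves open; `episcreen` fixes lower-inclusive,
   upper-exclusive bins with a closed top bin so the five bins partition
   [0, 100] exactly.
5. **Promoter CGI** — a CGI interval overlapping the same ±500 bp promoter
   window. Using the methylation window (rather than the ±2 kb H3K4me3
   window or an annotated CGI–gene map) keeps a single promoter definition
   throughout; this is an interpretation, recorded here deliberately.
6. **Expression validation** — criterion (a): expressed in normal colon
   (relative expression at least `expressedMin = 0.01` after housekeeping
   normalization — "expressed" needs an explicit numeric floor, which the
   qualitative phrase "expressed in normal colon" does not supply) and
   downregulated more than 2-fold in the tumor line; criterion (b):
   upregulated more than 2-fold by the demethylating drug **or** in the
   knockout derivative (a disjunction, per the screen's design; a
   conjunctive flag exists). Fold changes use a shared pseudocount
   `epsilon = 1e-3` so that `foldChange(x, x) = 1` and reactivation from
   complete silence registers as a large finite fold.

Stages are evaluated in this order, each only for survivors of the
previous stage; a transcript that fails early keeps `NA` ("not evaluated")
for later flags, so downstream sensitivity analyses can distinguish "failed
here" from "never reached". Gene-level results collapse transcripts by
`any_tss` (default: a gene silenced at any of its promoters is a
candidate); `all_tss` is available.

## Clinical statistics

Downstream of the screen, the package provides the cohort-level statistics
used to characterize a candidate marker:

- **Elevated methylation**: strictly above 15.0% in a clinical specimen,
  tabulated per group (normal, adenoma, advanced adenoma, carcinoma) with
  percentages formatted to one decimal, rounding half away from zero.
- **Group comparisons**: unpaired two-tailed Student's t test
  (equal-variance pooled statistic; Welch available as an option).
- **Methylation–expression correlation**: Pearson's product-moment r with
  the two-sided t-based p-value; significance at p < 0.01 (two-sided).
- **Survival**: Kaplan–Meier product-limit curves, the two-group log-rank
  test, and optimal-cutoff dichotomization (`findCutoff`). The cutoff
  finder scans midpoints between consecutive distinct marker values,
  requires at least 10% of samples on each side (avoiding empty groups and
  exact-tie ambiguity at observed values), and picks the cutoff minimizing
  the log-rank p — the "minimal p" member of the cutoff-optimization
  family; which member of that family produced any given published cutoff
  is typically unstated, so the variant is recorded in the result's
  metadata. Ties on p break toward the more balanced split, then the lower
  cutoff. The minimal p is reported **uncorrected**: the package's own
  null simulation (`generateNullClinical`) shows the fraction of null
  cohorts reaching p < 0.05 is far above 5%, the well-known optimism of
  cutoff optimization.

The t test, correlation, Kaplan–Meier estimator and log-rank statistic are
delegated to `stats` and `survival`; the test suite cross-checks the
log-rank and cutoff scan against independently hand-coded
observed/expected/variance computations.

## The synthetic study

`generateBundle()` produces a complete input bundle with a planted truth
set so every stage is verifiable offline. Its defaults define the study
conditions:

- **200 genes on one 10 Mb chromosome, 20 truly silenced.** One transcript
  per gene; a single chromosome keeps the bundle desk-scale while
  multi-chromosome handling is exercised by unit fixtures.
- **Beta-binomial bisulfite counts**: per-CpG site levels drawn from a
  Beta with concentration 50 around the planted promoter mean (0.85 for
  silenced tumor promoters, 0.05 for unmethylated promoters, 0.20 for
  tumor promoters of tissue-silent genes), read depth Poisson(30), about
  Poisson(12) CpGs per promoter. This is the standard bisulfite noise
  model and gives the 60%/40% filters realistic sampling variance to
  tolerate.
- **Chromatin**: silenced genes lack a parent-line H3K4me3 peak and carry
  one in the demethylated derivative; 39% of them also carry a parent-line
  H3K27me3 mark. Active genes have peaks in both lines with similar scores
  (log-normal, so quantitative ratios hover near 1); 20% of inactive
  unmethylated genes gain a derivative-line peak as chromatin noise, which
  the methylation filter must reject — this is what keeps precision a
  non-trivial property.
- **Expression**: normal-colon levels log-normal(0, 0.5) in relative
  units; silenced genes are reduced 8-fold in the tumor line and
  reactivated 6-fold under both drug and knockout; tissue-silent genes are
  reduced but *not* reactivated; inactive genes sit at 0.001, below the
  expression floor. Multiplicative log-normal noise (sd 0.2 on the log
  scale) perturbs every condition.
- **Clinical cohorts**: 46 normal / 38 adenoma / 41 advanced adenoma / 101
  carcinoma samples with Beta-distributed methylation around group means
  5 / 12 / 30 / 35% (concentration 8) — chosen so the >15% elevation rule
  yields frequencies rising from normal to carcinoma; the rising *shape*,
  not any particular percentage, is the testable property. Carcinoma
  samples carry exponential survival with a hazard ratio of 2 above the
  cohort methylation median and administrative censoring.

What the generator deliberately does **not** emulate: genome sequence
content and real CpG spacing, correlated methylation between neighboring
CpGs, read-level bisulfite conversion errors, multi-transcript genes,
copy-number or purity effects in clinical methylation, and non-proportional
hazards. Passing the recovery test therefore shows the pipeline's logic and
thresholds are mutually consistent under a realistic noise model — not that
the thresholds are optimal for any particular real dataset.

## Numerical and degenerate-input choices

- All on-disk interval formats are 0-based half-open (BED-native); internal
  containers are `GRanges` (1-based closed, the Bioconductor convention),
  converted only at the I/O boundary. The boundary tests pin the
  correspondence (a CpG at TSS+499 is inside the ±500 bp window, TSS+500 is
  not; a peak sharing exactly one base with a window is an overlap).
- The TSS of a minus-strand transcript interval is its last base (`end − 1`
  in 0-based coordinates) — the biological 5′ end, following UCSC practice.
- A window truncated at chromosome start is valid; a chromosome missing
  from a peak file yields all-negative calls, not an error; duplicate CpG
  positions within one tissue are an error (they surface upstream
  aggregation bugs), and unavailability of a promoter summary is a value,
  never an error.
- Percentages print with one decimal, rounding half away from zero, which
  reproduces conventional published roundings (e.g. 2175/10404 → 20.9%).
- Determinism: a bundle is a pure function of its configuration (including
  the seed); the suite checks byte-identical serialized bundles and exact
  write/read round trips (doubles serialized at 17 significant digits).

## Problem sizes used in validation

The shipped validation runs at sizes chosen to make each property sharp but
cheap: interval-overlap oracle equivalence on 1,000 randomized
configurations against a per-base brute-force scan; planted-truth recovery
on the default 200-gene bundle plus 20 replicate seeds (precision, recall
and mean F1 all ≥ 0.9 under the default effect sizes); funnel and
threshold monotonicity on 100 randomized bundles of 30–60 genes; the
cutoff-scan oracle on 50 random 30-sample cohorts, cutoff recovery on 100
replicates of a 200-sample cohort with a planted hazard-ratio-2 split, and
null-scan optimism on 300 replicates of 40-sample null cohorts.

## Known limitations

- The screen's counts on real data depend entirely on the supplied peak
  calls, RRBS coverage and annotation; the package consumes peaks and does
  not call them.
- The quantitative gain mode compares peak *scores*, whose meaning depends
  on the upstream peak caller; scores from different callers should not be
  mixed across cell lines.
- `findCutoff` reports an uncorrected minimal p by design; any use for
  inference (rather than exploratory dichotomization) needs a correction
  or validation cohort.
- Expression validation assumes one value per gene × condition; replicate
  handling (averaging, variance-aware tests) is upstream of this package.
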