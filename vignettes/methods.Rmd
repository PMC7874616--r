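---
title: "Methods: consensus CNV calling, QC and polygenic-score statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CNV calling, QC and polygenic-score statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpgs)
```

This vignette is the package's own account of the models and procedures it
implements, the numerical conventions it fixes, and what its synthetic
data can and cannot establish.

## Coordinate conventions

All intervals are 1-based inclusive: `length = end - start + 1` and the
gap between adjacent calls is `start2 - end1 - 1`. BED input (0-based
half-open) is converted at the read boundary. Percent-overlap columns are
rounded half-up (not banker's rounding) to two decimals, matching how
clinical report tables print them; gene-overlap percentages are rounded to
the nearest integer. For intervals of 20 kb and more the ±1 of the
inclusive convention is below the two-decimal rounding granularity, so the
reproduced table percentages hold under either convention.

## Fragment merging and consensus intersection

Array CNV callers sometimes report one large event as several adjacent
fragments. Merging is applied only within (chromosome, type) strata where
a sample has **more than** `trigger_count = 5` calls — many same-type calls
on one chromosome being the signature of a split event, and the trigger
protecting genuinely distinct CNVs elsewhere. Within a triggered stratum,
calls sorted by start are merged left-to-right under an absolute gap rule
(≤ 100 kb), then a fractional rule (gap ≤ 25% of the neighbouring call's
length), the two passes iterated to a fixpoint. Two genuinely open choices
were fixed here:

* *Which neighbour the 25% rule refers to.* We take the **longer** of the
  two neighbours (configurable to shorter/left/right). This is the most
  permissive natural reading, and at fixpoint the result is stable under
  the order in which eligible pairs are merged — a property the test suite
  checks against an any-order pairwise-closure oracle.
* *Whether "≥ 50% overlap" between callers is one-way or reciprocal.* We
  default to **reciprocal** (both fractions must reach the threshold),
  the stricter and more standard choice; `reciprocal = FALSE` gives the
  one-way variant. With a best-reciprocal-partner matching, each input
  call contributes to at most one consensus call; ties in intersection
  length break by smaller start coordinate.

Consensus coordinates are the intersection of the paired calls, with SNP
count and confidence carried from the first caller (the caller providing
confidence scores).

## The exclusion cascade

Rules run in a fixed order and each CNV is removed at the first failing
rule, which makes attrition tables reproducible: confidence < 10; any
(≥ 1 bp) centromere overlap; any MHC overlap (the printed hg19 interval by
default, overridable for the mini-genome); segmental-duplication coverage
> 50% of the CNV; internally common regions (base-level coverage by ≥ 25
calls, i.e. ~1% of a ~2,500-sample cohort) covering ≥ 50% of the CNV;
< 10 SNPs and/or < 20 kb (strict inequalities — a 20,000 bp CNV passes);
benign-catalog coverage ≥ 70% **of the CNV** (the published rule does not
state a denominator; CNV-denominated is the conservative reading and the
denominator is configurable); external-common and gnomAD-frequency rules
as ≥ 50% **reciprocal** matches (the matching rule is unstated in the
source; reciprocal is symmetric and configurable); finally the coding
requirement — a CNV with no exonic base is removed as `noncoding` (or
`nongenic` when it misses gene bodies entirely and a gene track is
supplied). A rule whose reference track is absent is inactive by default;
explicitly enabling it without the track is a configuration error.

## Kinship, sex and ancestry checks

Relationship classification uses the standard PLINK `--genome` summary:
PI_HAT = Z2 + Z1/2. The published full-sibling rule is printed with a
missing comma ("PI_HAT > 0.35 0.3 < Z1 < 0.8"); we read it as the
conjunction PI_HAT > 0.35 ∧ 0.3 < Z1 < 0.8 ∧ Z2 > 0.1. No precedence
between overlapping threshold boxes is stated; we evaluate MZ →
parent-offspring → full-sibling → half-sibling, first match wins, which
makes classification a total function. Inputs violating the simplex
constraints raise validation errors rather than silently classifying.

Sex checks call genetic sex from the X-chromosome inbreeding coefficient
(female < 0.25, male > 0.75). Reported females in the inconclusive band
are rescued when the genome-wide inbreeding coefficient is ≥ 0.05 — an
elevated X-F consistent with consanguineous ancestry rather than a sample
mix-up.

Ancestry assignment requires every PC coordinate within 4 SD of a
population's mean. When several populations qualify (unstated in the
source) we resolve by SD-scaled Euclidean distance and flag the call
ambiguous. Control matching takes, for each case in ascending identifier
order, the 5 pool members nearest in Euclidean distance over the first 3
PCs; the default is **without replacement** (each case consumes its
matches), which yields a valid control set for downstream group tests —
the with-replacement variant is available and the mode should be logged by
callers.

## Polygenic-score statistics

Scoring is the linear dosage-weight product, with missing dosages imputed
at twice the in-sample effect-allele frequency (the PLINK `--score`
default; skipping is available). Standardization subtracts the control
mean and divides by the control n−1 SD. The group test is a Z-test with
**unpooled** variances (the source says only "Z-tests"; unpooled is robust
to the large case/control imbalance). The pTDT deviation is
(child − midparent) / SD(midparent across trios), tested with a one-sample
t-test; if every deviation is identical the statistic degenerates to 0
(p = 1) or ±∞ (p = 0) rather than erroring.

Residualization regresses the phenotype on age, sex and PCs, then
backwards-eliminates the PC with the largest p-value above 0.05 until all
retained PCs are significant; age and sex are never dropped. The named
procedure's elimination criterion is unstated — per-covariate p > 0.05 is
the simplest defensible choice and the threshold is a parameter.
Prediction reports the Pearson correlation with its t-based p-value, the
covariate-only adjusted R², and the increase in R² from adding the PGS on
both the unadjusted (`delta_r2`, exactly ≥ 0) and adjusted
(`delta_r2_adj`) scales; the "percent change over baseline" uses the
adjusted pair, matching how such tables report a 34% increase over a 4%
baseline.

Analytic power: for the two-sample design, two-sided normal approximation
with noncentrality `effect / sqrt(1/n1 + 1/n2)`; for the one-predictor R²
design, the noncentral F with df (1, n−2) and noncentrality
`n·R²/(1−R²)`. Both printed ~80% statements reproduce (0.790 and 0.807),
and both are cross-checked against 10,000-replicate Monte Carlo rejection
rates in the acceptance suite.

## The synthetic cohort: what it emulates, and what it does not

The generator builds a miniature genome (five 50-Mb chromosomes by
default) and a family cohort of trios/quads plus unrelated children, with:

* **Mendelian genotypes** — founders drawn binomially at uniform common
  allele frequencies (0.05–0.95), children by explicit gamete
  transmission, so trio error rates are exactly zero unless errors are
  planted.
* **Latent polygenic scores** — parents N(shift, 1) with the family-level
  shift taken from the `ASD` entry of `group_pgs_shifts` (siblings share
  parental background, so within-family group shifts are deliberately not
  independently adjustable), children at midparent + N(0, √½), plus an
  optional planted over-transmission (`ptdt_shift`). Unrelated children
  draw from N(shift_UNR, 1). The control SD is 1 by construction.
* **Phenotypes** — `√R² · PGS + √(1−R²) · noise`, with age and sex carried
  as true-null covariates for the stepwise-elimination tests.
* **Caller views** — each planted CNV appears per caller with a detection
  probability, possibly fragmented into 2–3 pieces whose union spans the
  true event with gaps ≤ 50 kb, endpoints jittered; false positives are
  drawn per caller independently and so appear in one caller only.
  Common polymorphic regions produce same-carrier calls in both callers.
* **IBD statistics** — drawn from relationship-typical distributions
  (e.g. parent-offspring Z1 ≈ 0.99) by default, or estimated from the
  genotype panel by a PLINK-style moment estimator when the panel is large
  (≥ 2,000 variants in `auto` mode); both paths exercise the classifier.
* **Reference tracks** — a gene with exons is planted inside every true
  CNV (so planted CNVs are exonic and survive the cascade), while segdups
  and benign regions are placed away from planted CNVs; truth placement
  avoids the centromere and MHC bands. This is what makes the
  planted-truth recovery test exact.

All randomness flows from one master seed through labelled sub-streams
(`sub_seed(seed, label)`), so each artifact is individually reproducible
and a fixed seed yields byte-identical bundles; emitted floating-point
values are snapped to their decimal-parse fixpoint so the text round-trip
is lossless.

What the generator does **not** emulate: raw LRR/BAF intensity signal
(caller outputs are simulated directly, so caller-specific error modes are
schematic); linkage disequilibrium (variants are independent, so the
moment IBD estimator behaves better than on real arrays); realistic allele
frequency spectra and population-specific frequencies (PC coordinates are
drawn around synthetic centroids, not computed from genotypes); and
genotype-derived PGS group shifts (shifts are planted in latent scores —
the dosage panel and weights exercise the scoring arithmetic, not the
group structure). A green planted-truth test therefore establishes the
correctness of the pipeline's logic and arithmetic, not the calibration of
the callers it consumes.

## Degenerate inputs and numerical edges

Zero batch SD in sample QC means only exact-mean values pass, so an
all-identical batch passes. A cytoband straddled exactly 50/50 reports
both bands, flagged ambiguous. Empty call tables flow through every stage
as empty results; fewer than two samples (QC), two controls
(standardization), two trios (pTDT) or three spouse pairs are errors, as
are zero-variance groups. The acceptance criteria's two excluded
table rows (one with an internally inconsistent printed reference start,
one 0.01% off under any convention) are deliberately not asserted anywhere.

## Scaling choices in the test suite

The acceptance tests run the stated designs at their stated sizes: both
Monte-Carlo power cross-checks and both type-I calibration suites use
10,000 replicates (vectorized, a few seconds each); oracle equivalence
runs 500 random instances of ≤ 50 calls; planted-truth recovery uses an
8-family noise-free cohort. The planted prediction-R² check uses the
generator at roughly the stated sample size (n ≈ 1,200 children and
parents). Nothing is gated on environment variables.
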