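---
title: "Methods: measuring X-chromosome dosage compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring X-chromosome dosage compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdosage)
```

## The problem

Therian sex chromosomes evolved from an ordinary autosome pair. As the Y
decayed, X-linked genes were left with a single functional copy in males
(and one active copy in females after X inactivation). Ohno's hypothesis
holds that X-linked expression was up-regulated roughly two-fold to
restore the ancestral output. Two observables test it:

* **X:AA** — the mean expression of X-linked genes divided by the mean
  expression of autosomal genes within one sample context (a tissue, a
  developmental stage, or both). Under full compensation X:AA is near 1,
  but it also moves with the *gene content* of the X: an excess of
  tissue-specific, stage-trending or silent genes shifts the ratio
  without any change in per-gene regulation.
* **X:XX** — the expression of current X-linked genes relative to their
  1:1 orthologs in an outgroup that diverged before the sex chromosomes
  arose (a proxy for the unobservable proto-X). This is the direct test:
  a median near 1 means the ancestral output was maintained; a median
  near 0.5 means it was halved.

The package implements both estimators, the specificity and
stage-correlation analyses that explain X:AA dynamics, the bin-matched
proteome comparison, and a promoter chromatin-state analysis — plus a
synthetic-data generator whose ground truth makes every stage testable
without external downloads.

## Estimators and conventions

**X:AA** (`xaa_ratio()`) is a *ratio of means*, not a mean of per-gene
ratios; the two differ substantially under the heavy right skew of FPKM,
and the ratio-of-means convention is fixed throughout. Genes are
filtered per context at an expression cutoff before the means: a gene is
*expressed* when its value exceeds the cutoff (strictly), *unexpressed*
when value <= cutoff. The conventional cutoff is FPKM > 1; cutoff 0
("the zero cutoff") retains genes with any expression, and an all-genes
sentinel applies no filter. A gene's value within a context is its mean
over the selected samples — replicates are pooled before the ratio, not
averaged into sub-ratios (`samples =` exposes any other grouping).

**Bootstrap CI** (`bootstrap_xaa()`): 1000 replicates each draw, without
replacement, a set of autosomal genes *size-matched* to the filtered X
set and recompute mean(X)/mean(sampled A); the X set is held fixed. The
90% interval spans the nearest-rank empirical percentiles
(`ceiling(p * n)`-th order statistics), so results are bit-reproducible
under a fixed seed. These error bars describe the sampling variability
of the autosomal reference only. They do not cover noise in the X-side
mean, which with a few hundred heavy-tailed X genes is comparable in
size — so the realized coverage of the true ratio sits a few points
below the nominal 90% (about 85% under the default synthetic
conditions), and a single dataset's X:AA can sit visibly off its ground
truth while the CI is narrow. With-replacement resampling is available
as a sensitivity flag.

**X:XX** (`xxx_pipeline()`) runs a fixed order: classify pairs ->
attach context expression -> filter -> scale -> normalize -> median.
Pair classes: an *X pair* joins a focal X-linked gene to an ortholog on
an allowed outgroup autosome (for a chicken-like outgroup, chromosomes 1
and 4, which carry the orthologs of the mammalian X); an *AA pair* joins
autosomal genes, excluding orthologs on the outgroup's own sex
chromosomes (Z/W). A marsupial-style rule can treat the outgroup X as an
ordinary autosome pair (its X is biallelically up-regulated in the
opossum). Both members of a pair must pass the cutoff — the X carries
more silent genes, and requiring expression on both sides keeps the
comparison fair. Outgroup values are then rescaled so the two species'
medians over all retained pairs coincide; per-pair ratios are normalized
by their AA-pair median (making AA:AA exactly 1 by construction), and
X:XX is the *median* of the normalized X-pair ratios. Because the AA:AA
normalization cancels any global factor, X:XX is invariant to rescaling
the outgroup matrix, and the choice of pooling X and AA pairs in the
species-scaling median is immaterial (a test asserts both). Scaling is
per-tissue by default; a shared global factor can be obtained by scaling
once on pooled contexts.

**Tau specificity** (`tau()`): for a profile $x_1..x_n$ over $n$
contexts, $\tau = \sum_i (1 - x_i/\max_j x_j)/(n-1)$, 0 for uniform
expression and 1 for single-context expression. Tissue profiles are
per-tissue means across that tissue's stages, on raw FPKM (a
`log_transform` option exists because part of the tau literature logs
first; logging compresses dynamic range and lowers tau). All-zero genes
are excluded rather than given a value. Stage specificity applies the
same formula to per-stage means within one tissue; because tissues cover
different numbers of stages, those values are not comparable across
tissues and the package does not offer such a comparison.

**Tissue-specific genes**: no standard criterion exists, so the package
uses the conventional tau > 0.8 with assignment to the
maximum-expression tissue (ties broken toward the alphabetically first
tissue and flagged). The threshold is a parameter; lowering it grows the
sets but mixes in broadly expressed genes, and recovery tests show
near-perfect recall of simulated specific genes at 0.8 under default
noise.

**Stage-correlated genes** (`stage_correlation()`): per-gene Spearman
correlation between expression and stage rank, replicates within a stage
sharing a rank (average-rank ties). Classes use rho > 0.8 (or < -0.8)
with raw p < 0.05 — multiple-testing correction is off by default to
match the raw-p convention, with a BH option. p-values are exact by full
permutation enumeration up to 9 samples and use the t approximation
above; constant genes are reported with missing rho rather than
dropped silently. The threshold sweep reports, for each sign, the
X-linked fraction *among classified genes* against the X share among all
genes; a flag switches to per-chromosome classified fractions, the other
reading of that summary.

**Exact tests**: Fisher's exact p sums hypergeometric probabilities no
larger than the observed table's; the rank-sum test enumerates group
labelings exactly up to a combined n of 20 and otherwise uses the
normal approximation with tie and continuity corrections. These
primitives are implemented in the package so their small-sample behavior
is exact and reproducible; unit tests cross-check them against the
independent base-R implementations and brute-force oracles.

**Proteome bins** (`quantile_bins()`): X-linked and autosomal
abundances are separately sorted descending (ties broken by gene id) and
split into 100 near-equal bins, remainder to the highest-abundance bins;
only the top 25 bins are compared, bin against bin, reflecting the
limited coverage and resolution of mass spectrometry at low abundance.
The per-tissue summary is the median of the 25 bin ratios (mean
available by flag).

**Promoters and chromatin states** (`promoter_intervals()`,
`intersect_states()`): promoters are TSS -2 kb / +1 kb, strand-aware.
All external coordinates are BED-convention 0-based half-open; on the
minus strand the window is reflected so "upstream" follows
transcription, with the TSS base itself on the downstream side on both
strands: for a TSS at t the window is `[t - 2000, t + 1000)` on the plus
strand and `[t - 999, t + 2001)` (that is,
`[t - downstream + 1, t + upstream + 1)`) on the minus strand. Windows
are clipped at position 0. A promoter overlapping a state segment by at
least 1 bp is annotated by that state; per-gene diversity is the number
of *distinct* states across all epigenomes (a summed per-epigenome count
is available by flag, the other reading of "number of states"), and
per-chromosome base fractions are computed over promoter bases (the
quantity the intersection actually measures).

## The synthetic-data generator

`simulate_expression()` and friends emulate exactly the statistical
structure the analyses assume:

* Per-gene baselines are log-normal (meanlog `log(20)`, sdlog 1 by
  default) — FPKM distributions are heavy-tailed, and log-normal is the
  simplest emulator that makes the ratio-of-means behavior predictable.
  The baseline level is chosen so the FPKM > 1 filter truncates
  negligibly; truncation, not the ratio arithmetic, is what would
  otherwise bias recovery at low compensation factors.
* The compensation factor multiplies every X-linked gene relative to its
  own ancestral level, so X:AA and X:XX share one ground truth. The
  outgroup expresses the *ancestral* (pre-compensation) expectation of
  every gene — including its tissue and stage patterns — times a global
  species scale and log-normal noise, with orthologs of X genes placed
  on outgroup autosomes. Ground-truth X:XX equals the compensation
  factor; ground-truth AA:AA is 1.
* Divergence between X:AA and X:XX is induced only through gene-content
  fractions: tissue-specific genes (at baseline in one assigned tissue,
  at 1% of baseline elsewhere), monotone stage-trending genes (log-linear
  ramp over stage rank spanning an 8-fold range, geometric mean 1 —
  Spearman-based detection depends only on monotonicity, so the ramp
  shape is immaterial), and unexpressed genes (exactly 0 everywhere).
  `sim_params_divergence()` packages the headline condition: full
  compensation, half of X genes testis-specific, X-enriched rising
  genes, excess silent X genes. Under it the zero-cutoff X:AA spans from
  below 0.7 (tissues where the X's specific genes are off and drag the
  mean) to above 1.1 (testis), while X:XX stays within a few percent of
  1 in every tissue — the generator-level restatement of the claim that
  gene content, not compensation, drives X:AA dynamics.
* Chromatin: each gene carries a fixed palette of chromHMM states
  (default 12 for X, 9 for autosomes, always including 15_Quies);
  promoters are tiled in 200-bp segments drawn from the palette with a
  class-specific quiescent share (50% on X, 30% on autosomes), the rest
  of the genome is quiescent, and overlapping promoters are truncated so
  every epigenome is a valid segmentation.
* The proteome is mRNA^b times log-normal noise (b = 1, sdlog 0.5);
  zero mRNA gives zero protein.
* Everything is deterministic under one seed, fanned out to per-stage
  seeds by hashing stage labels (`derive_seed()`), so no generator or
  bootstrap consumes wall-clock entropy.

What the generator does *not* emulate: count-level (Poisson/NB)
sampling noise, gene length and mappability effects, correlated
co-expression modules, partially silenced genes (silent means exactly
zero), ortholog misassignment, or annotation disagreements between
species. Passing recovery tests therefore shows that the estimators are
correct and well-calibrated under the assumed generative structure, not
that real-data confounders are handled; on real matrices the filters and
normalizations are the only defenses, as in the underlying study design.

## Numerical choices and degenerate inputs

* CI percentiles: nearest-rank order statistics (documented above), so
  the 90% interval nests inside the 99% one for the same replicates.
* Bin and max-tissue ties: broken by gene id / alphabetical tissue,
  flagged where scientifically meaningful.
* Empty classes: a cutoff that empties the X or autosome set is an
  error in `xaa_ratio()` and recorded as a missing entry by
  `ratio_cutoff_series()`; an all-zero profile is an error in `tau()`
  and an exclusion in the table-level wrappers; a zero autosomal bin
  mean yields a missing bin ratio; a zero-margin 2x2 table is an error.
* Expression TSVs are written with 17 significant digits so write/read
  round trips are bit-exact; malformed cells fail loudly with gene and
  sample named, and genes absent from the annotation are dropped with a
  logged count (real annotation releases routinely disagree).

## Problem sizes

The test and acceptance workloads use 2000 autosomal + 200 X genes
(log-sd 1.0) with 20 seeds for recovery of compensation factors 0.5,
0.75 and 1.0, 100 seeded runs for CI coverage, a 4000 + 400-gene
divergence dataset, and 150 genes x 50 epigenomes for chromatin
recovery — sizes at which the recovery tolerances (±0.05 on ratios) sit
several standard errors wide for X:XX and about two for X:AA. The
analysis scripts under `analysis/` run the same pipeline end-to-end from
generated TSV/BED files at the divergence condition.

## Known limitations

* The X:AA bootstrap interval intentionally mirrors the
  autosome-resampling error-bar semantics; it is not a confidence
  interval for the estimator's total error (see above).
* Counts of "tissue-specific genes" depend entirely on the tau
  threshold; they are reported with the threshold attached and should
  not be compared across thresholds or preprocessing choices.
* Stage-specificity values are not comparable across tissues with
  different stage coverage, and the package provides no such view.
* Chromatin analyses consume published segmentations as-is; no
  model training, liftover, or assembly reconciliation is performed.
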