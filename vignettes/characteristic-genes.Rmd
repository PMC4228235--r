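---
title: "Methods: characteristic developmental genes and over-representation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characteristic developmental genes and over-representation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargenes)
```

This vignette is the package's account of its statistical machinery: the
models, the conventions that had to be pinned down, and what the synthetic
benchmarks do and do not demonstrate.

## The data model

Expression is handled as a wide table — a `feature_id` column plus one
numeric column per sample — holding log2-scale normalized intensities
(RMA-style signals or equivalents). Upstream normalization from raw array
files is out of scope: the package starts where a normalized matrix ends.
Sample metadata carries a single monotone age axis in days. Where a study
mixes embryonic and postnatal labels, prenatal ages enter as days post
conception and postnatal ages as gestation length plus postnatal day (the
simulator uses 19.5 days, a typical mouse gestation); the merge rule is the
caller's responsibility since platforms annotate age inconsistently.
Features with missing values are removed before analysis by
`drop_incomplete_features()`, with a reported count; analysis entry points
refuse non-finite values rather than guessing.

## Probe-to-gene collapse

Array platforms measure many genes with more than one probe set, and a
single representative must be chosen before gene-level analysis.

* **Time series**: the representative is the probe with the maximum Pearson
  correlation between its two replicate age profiles. Reproducibility
  across biological duplicates is a direct measure of signal quality for a
  temporal profile. Zero-variance profiles yield an undefined (`NA`)
  correlation and lose to any probe with a defined one.
* **Paired designs**: the representative is the probe with the smallest
  signed-rank p-value.

Both rules need a deterministic tie-break; the lexicographically smallest
probe id is used. Ties have measure zero in real intensities but occur in
rounded inputs, and determinism is required for reproducible artifacts.
Exactly two replicates are supported for the correlation rule — the designs
this pipeline targets are biological duplicates — and mismatched age grids
are an error rather than an alignment problem the package should solve
silently.

## Characteristic genes from loading magnitudes

Let X be the N genes × M samples matrix after two preprocessing steps:

1. **Column standardization** — each sample is centered and scaled to
   variance 1. The analysis concerns sample variation in the sense of
   correlation, not Euclidean distance; standardization removes per-sample
   intensity scale. The variance denominator is the sample variance
   (n − 1); since every column has the same length this choice rescales all
   columns by the same factor and cannot affect component directions, but it
   is pinned for bitwise reproducibility.
2. **Gene centering** — each gene is centered across samples, so the
   decomposition describes the sample cloud about its centroid. An
   uncentered decomposition otherwise devotes its first component largely to
   the mean profile; `center_genes = FALSE` is available for sensitivity
   analysis.

The SVD X = U D Vᵀ then gives, for component k, the gene-space direction
U[, k] (the loadings), sample scores D[k, k] · V[, k], and explained-variance
fraction d\_k² / Σ d\_i². A gene's |loading| measures its contribution to
sample variation along that component. Within each component genes are
ranked by decreasing |loading| (rank 1 = largest; ties by gene id), and the
characteristic set of the dataset is the union over PC1–3 of the top 5% of
genes per component. Both the fraction and the component set are arguments;
the defaults follow the convention that the first three components of a
developmental series track age, time-to-birth and stage transitions. The
per-component count is `round(top_fraction * N)` rounded half-up — a pinned
choice, since "top 5%" alone does not determine a count. Component signs
are arbitrary; the implementation fixes each sign (largest-|loading| gene
positive) so outputs are stable, and all downstream quantities depend only
on |loading|. Whether to collapse probes to genes before or after this step
is left to the caller; the documented default workflow ranks collapsed
gene-level matrices.

## Paired differential expression

For each feature, within-pair differences d\_i (condition A minus B) are
tested with the Wilcoxon signed-rank statistic W = sum of ranks of positive
differences after ranking |d| with midranks. Conventions, all echoed into
the result metadata because statistical environments differ here:

* zero differences are discarded before ranking (the classical convention);
  `zero_handling = "keep"` retains them Pratt-style and always uses the
  normal approximation;
* the p-value is exact (signed-rank null distribution) when the retained
  n ≤ 25 with no tied magnitudes, otherwise a normal approximation with
  tie-corrected variance and a 0.5 continuity correction;
* a feature whose differences are all zero is degenerate: p = 1, flagged,
  never significant;
* significance is strict raw p < α (default 0.05) with no multiplicity
  adjustment — the over-representation stage consumes the raw significant
  set — but a Benjamini–Hochberg column is reported for context.

The log2 fold change is the arithmetic mean over A samples minus the mean
over B samples, which is the log2 ratio of geometric-mean intensities.

## Over-representation inference

Two gene sets A and B inside an explicit measured universe U (all genes on
the platform after collapse — always an argument, never inferred) define the
2×2 table (a, b, c, d). Conditioning on all margins, the overlap count a
follows a noncentral hypergeometric distribution with noncentrality the
odds ratio ψ; everything below is computed from that distribution, on the
log scale for stability.

* **Two-sided p** — point-probability rule: the sum of probabilities of all
  support values whose probability does not exceed the observed one
  (relative slack 1 + 1e−7), the convention of the mainstream exact-test
  implementations; the doubled-one-sided rule is available behind a flag.
* **Point estimates** — the cross-product ad/bc is printed first (it is the
  estimate the reproduced analyses print), with the conditional MLE —
  the ψ solving E\_ψ[a] = observed a, found by monotone root-finding on
  log ψ to relative tolerance 1e−8 — always alongside. At the support
  boundary the CMLE is 0 or ∞ by monotonicity of the likelihood.
* **Confidence interval** — two conditional methods:
    * `"cornfield"` (default): continuity-corrected inversion of the
      conditional distribution using its exact mean and variance; the
      bounds solve (|a − E\_ψ(a)| − ½)² / Var\_ψ(a) = z²\_{α/2} on either
      side of the point estimate. This is the method whose bounds agree, to
      printed precision, with the published intervals the package
      reproduces, which is why it is the default.
    * `"exact"`: tail inversion — the lower bound solves
      P(a ≥ a\_obs | ψ) = α/2 and the upper bound P(a ≤ a\_obs | ψ) = α/2.
      These bounds put exactly α/2 in each conditional tail (a property the
      test suite verifies by direct summation) and are never
      anti-conservative, at the price of over-coverage typical of exact
      intervals. On the headline tables the two methods differ in the
      second decimal (for the table (12, 26, 2685, 17465): 1.43–6.21
      continuity-corrected versus 1.38–6.17 exact).

  When the observed overlap sits at the boundary of its support the
  corresponding bound is 0 or ∞, flagged rather than truncated.

```{r headline}
enrich_from_counts(overlap = 12, size_a = 38, size_b = 2697,
                   size_universe = 20188)
```

Gene-set assembly (`assemble_union_set()`) merges "supervised"
(literature/ontology-derived) and "unsupervised" (stimulation- or
ChIP-derived) lists into one set with per-gene provenance flags and reports
their intersection. Live ontology or gene-database queries are deliberately
excluded: they are database-version dependent and belong upstream of a
reproducible pipeline.

## Local-regression smoothing

`smooth_profile()` fits a locally weighted polynomial (tricube weights over
the span-nearest neighbours) to one age profile and evaluates it at the
observed ages, to damp subject- and age-estimation-related variation before
modelling global developmental patterns. Defaults — span 0.7, local linear —
are deliberately gentle: the fit reproduces polynomials up to its degree
exactly, so a linear trend passes through untouched. The smoother is
provided generically and not wired into any stage by default
(`smooth$enabled` in the pipeline config), because which dataset of a given
study should be smoothed is a judgement about measurement quality, not a
property of the method. A span too small to cover degree + 1 points is an
error.

## The simulators: what they emulate, and what they do not

`simulate_dev_timeseries()` emulates a duplicated whole-organ series:
15 default timepoints spanning E9.5–P56 on a days axis, two replicates,
per-gene Gaussian baselines, and a planted minority of genes carrying a
temporal program shared across replicates — a logistic ramp (75% rising, so
most planted genes are higher late in development), a sharp stage switch,
or a transient pulse, with midpoints confined to the central 60% of the age
window so every program acts inside the sampled interval. Defaults: 2,000
genes, 100 planted (5%, matching the top-5% selection rule so recovery is a
fair one-to-one comparison), amplitude 1.5 log2 units (a 2.8-fold swing,
typical of developmental regulation), noise sd 0.5 log2 units — a 3:1
amplitude-to-noise ratio. `simulate_paired_cohort()` emulates a
sibling-pair-scale design: 95 pairs, a shared within-pair shift (sd 0.5)
inducing the pairing correlation, planted effects of +1 log2 unit in 5% of
genes, noise sd 0.4. `simulate_probe_map()` gives each gene 1–3 probes, one
designated low-noise probe per gene, so both collapse rules have a planted
truth.

Noise is additive Gaussian on the log2 scale — the conventional log-normal
intensity model. The simulators do **not** emulate batch effects,
platform-specific probe behaviour, intensity-dependent variance, correlated
gene modules beyond the planted programs, or annotation error.
Consequently, passing recovery and calibration benchmarks shows the
pipeline's operations are correct and well calibrated under the model it
assumes; it does not certify performance on real arrays, where those
un-modelled features are the main hazards.

All generators are pure functions of their configuration including the
seed; identical seeds give bit-identical output.

## Benchmarks the test suite runs

Problem sizes were chosen so the full suite completes in a few minutes on a
single core while keeping Monte-Carlo error small relative to every margin
tested:

* Fisher p-values are checked against direct-summation enumeration for
  every margin configuration with table total ≤ 200 (every distinct table,
  using transposition symmetry, which is itself asserted), at 1e−12.
* Exact CI bounds are audited by direct tail summation at 1e−6.
* Signed-rank exactness is checked against full 2ⁿ sign-flip enumeration
  for every n ≤ 12; the type-I error of the full differential-expression
  stage is measured on 50 null cohorts of 2,000 features × 95 pairs
  (100,000 tests) against a 3-standard-error band around the nominal 0.05.
* Characteristic-gene recovery is measured over 20 seeded series at the
  default 3:1 amplitude-to-noise ratio (≥ 90% of planted genes in the
  top-5% PC1–3 union) and at amplitude 0, where recovery must fall back to
  the chance level implied by the union size.

## Known limitations

* The correlation-collapse rule supports exactly two replicates; series
  with more replicates need a caller-supplied reduction first.
* The normal-approximation branch of the signed-rank test is slightly
  conservative near n = 26–50 compared to the exact distribution; the
  switch point (25) is pinned for compatibility, not optimality.
* The Cornfield continuity-corrected interval is an approximation; its
  bounds can fall slightly inside the exact tail-inversion bounds. Both are
  one function argument apart, and every result records which was used.
* Characteristic-gene selection is rank-based and ignores loading
  uncertainty; near the top-5% cut the membership of individual genes is
  unstable under resampling, which is why recovery is scored on the union.
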