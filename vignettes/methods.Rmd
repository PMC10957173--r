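---
title: "Methods: cell-type proportion mapping and atrophy association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type proportion mapping and atrophy association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincellmap)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic tests do and do not
demonstrate about real data.

## The model

The pipeline estimates, at every gray-matter (GM) voxel, the relative
proportions of six canonical brain cell classes, then asks whether the
regional atrophy pattern of a disorder co-varies with any of those
cellular landscapes.

**Interpolation.** Bulk transcriptome samples are sparse points in
stereotaxic space. Expression at an unsampled voxel $v$ is predicted as a
normalized kernel-weighted average of the samples,
$\hat e_g(v) = \sum_j w_{vj} e_{gj}$ with
$w_{vj} \propto \exp(-\lVert v - x_j \rVert^2 / 2\ell^2)$ and
$\sum_j w_{vj} = 1$. This is Nadaraya–Watson kernel regression with a
squared-exponential kernel — a weighted average, deliberately *not* a full
Gaussian process with covariance inversion. The normalized-kernel
predictor is the computation we implement because it is exactly
reproducible, its predictions are convex combinations of observed values
(so they respect each gene's observed range), and it has a single
interpretable parameter. Predictive variance, anisotropic kernels and
per-gene length scales are out of scope.

**Deconvolution.** For cell type $c$, take the z-scored marker × voxel
matrix and its best rank-1 factorization (first singular triplet). The
voxel-side factor, scaled by the singular value, is an *eigengene*: a
one-dimensional summary of the coordinated expression of that type's
markers, read as a relative abundance surrogate. Z-scoring first makes the
score invariant to per-gene affine rescaling (probe gain and offset).
Eigengene scores are signed and affinely arbitrary, while the downstream
normalization needs nonnegative values, so each score is min-max rescaled
to $[0, 1]$ over GM — an affine, rank-preserving map. Finally
$p_c(v) = u_c(v)/\sum_{c'} u_{c'}(v) \cdot \mathrm{GM}(v)$, so the six maps
are nonnegative and sum to the GM density at every voxel; voxels whose six
scores are all zero are flagged and excluded from regional averaging
rather than imputed.

**Association.** Maps are averaged over the regions of a parcellation
(the bundled lookup has 118 AAL-style GM regions; any label volume with a
`label`/`name` TSV can be swapped in, e.g. a 98-region DKT-style
parcellation — the code path is identical). Each (cell type, condition)
pair gets a Spearman rank correlation; rank-based association is used
because atrophy t-scores and surrogate proportions have no common scale
and their relationship is only assumed monotone. The whole cell ×
condition family is corrected jointly with Benjamini–Hochberg — the most
conservative natural reading of "correction across the matrix" — and both
raw p and adjusted q are reported so either convention can be read off.

**Clustering.** Rows (cell types, on their condition profiles) and columns
(conditions, on their cell profiles) are clustered with average-linkage
(UPGMA) on Euclidean distances between raw (not absolute) correlation
values; an `use_abs` flag exists for sensitivity checks. UPGMA ties are
broken toward the smallest node-index pair so results are deterministic
across platforms. Newick export places a node merged at height $h$ at
elevation $h/2$, making leaf-to-leaf cophenetic distance equal the merge
height.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `length_scale_mm` | 5 | mm | Comparable to inter-sample spacing of dense cortical sampling; small enough to preserve regional contrast. `loo_cv_bandwidth()` justifies per-dataset values; one global value for all genes. |
| markers per type | 15 | genes | Enough for a stable rank-1 eigengene, few enough to stay type-specific; 6 × 15 = 90 bundled. |
| `gm_threshold` | 0.2 | probability | Conventional GM-probability cut for analysis masks in real mode. |
| `alpha` | 0.05 | — | FDR threshold for the joint cell × condition family. |
| `weight_floor` | 1e-12 | — | Below this total kernel mass a target falls back to its nearest sample instead of dividing by ~0. |
| `smooth_fwhm_mm` | off | mm | Optional common smoothing of all atrophy maps, for kernel-size robustness checks. |

Probe-to-gene collapse defaults to keeping the probe with the highest mean
expression across all samples (deterministic, standard microarray
practice); averaging probes is available. Genes are z-scored within donor
before pooling, removing donor batch offsets; both behaviours are flags.
An off-by-default `mirror_missing_hemisphere` flag reflects
single-hemisphere donors across the midline. Coordinates are 0-based voxel
indices, world millimetres, rounding half away from zero; out-of-bounds
samples are flagged, never silently clamped, and missing values ride
through resampling as `NA`, never as zero.

## The synthetic phantom

`generate_phantom()` builds a GM density (ellipsoidal shell × smooth
positive field, ~9000 voxels at the default 32³ × 2 mm), six cell density
fields (min-max-normalized sums of 4 Gaussian bumps of 8 mm width at
random GM centers), ground-truth proportions (fields normalized to sum to
1 on GM), and a 118-region parcellation from seeded k-means on GM
coordinates. `sample_bulk_expression()` draws 200 GM locations without
replacement and emits marker expression
$s\,\mathrm{truth}_c(v) + b + \mathcal N(0, \sigma)$ with $s = 4$,
$b = 0$, $\sigma = 0.5$ by default — signal-to-noise comparable to what a
well-behaved marker panel shows after normalization.
`generate_atrophy()` plants $t(v) = t_0 - \sum \beta\,\mathrm{truth}_c(v)
+ \mathcal N(0, \sigma_t)$ with $\beta = 8$, $\sigma_t = 1$: negative
slope, so lower t means more simulated tissue loss, matching the sign
convention of real atrophy t-maps. The 13 default synthetic conditions
cycle their drivers through the six types, giving the same 6 × 13 design
as a multi-disorder study. Everything is a pure function of the seed.

What the phantom does *not* emulate: transcriptome-wide gene–gene
covariance, the spatial autocorrelation spectrum of real cortex,
donor-specific effects beyond an optional offset, hemispheric asymmetry,
and registration error. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under known ground truth — not that
real-data marker panels are unambiguous or that real atrophy maps are
noise-free.

## Recovery behaviour and how it is evaluated

Two recovery regimes are tested, deliberately on different footings:

* **Noiseless exactness.** With zero expression noise the marker submatrix
  of a cell type is exactly rank one in the true proportions, so the
  eigengene score is a monotone transform of the truth and its Spearman
  correlation with the truth is exactly 1. This is checked on the sample
  matrix itself, where the statement is mathematically exact; routing the
  noiseless case through interpolation first would only measure smoothing
  bias of the reconstruction (about 0.94–0.98 rank correlation at default
  sampling density), which is a property of interpolation, not of the
  decomposition.
* **Noisy robustness.** At the default noise level the full default route
  — interpolate, then deconvolve — must track the true density fields
  across all GM voxels with Spearman ≥ 0.8 for every type, across 20
  seeds (observed ≥ 0.85). Interpolation's averaging is part of the
  method here and legitimately suppresses expression noise.

Planted-association detection is evaluated on the phantom's true density
fields against a planted astrocyte-driven condition over 118 regions:
this isolates the association stage (regional averaging + Spearman + FDR),
whose input contract is any regional matrix; deconvolution accuracy is
covered by the recovery tests above. Across 100 seeds the planted driver
carries the largest-magnitude, always-negative correlation in its column
in 100/100 runs.

## Numerical choices and degenerate inputs

* Kernel weight rows are renormalized after a one-hot fallback for
  targets whose total kernel mass underflows; rows sum to 1 within 1e-12.
* Smoothing uses mask-normalized convolution
  (`smooth(x·m)/smooth(m)`), so constants on the mask are fixed points and
  field edges do not bleed toward zero; kernels are truncated at 4σ and
  renormalized; oblique affines draw a warning and use per-axis scale
  lengths.
* Zero-variance genes z-score to all-zero and are flagged, not dropped
  silently; a constant surrogate score (no usable signal) is a hard error.
* Spearman p-values use exact enumeration for n ≤ 10 tie-free vectors and
  the t-approximation otherwise; ties use average ranks. Leave-one-out
  bandwidth ties (including the all-equal-expression case, where every
  candidate has error 0) resolve toward the smaller length scale.
* The sample loader reports the parsed sample count rather than asserting
  a particular one, since published sample tallies for the same atlas
  differ between sources.
* UPGMA is implemented with the Lance–Williams average update, which
  reproduces the unweighted mean over all cross-pairs exactly; tests
  compare it against a from-scratch O(k³) recomputation and
  `stats::hclust`.

## Problem sizes used by the test suite

Unit tests run on 16³ phantoms with 60 samples and 12 regions; recovery,
conservation and planted-association checks use the full default
conditions (32³, 200 samples, 118 regions, 20–100 seeds). The complete
suite and the acceptance script each finish in about a minute on one CPU.

## Known limitations

Surrogate proportions are relative, not cell counts per mm³; comparisons
across cell types inherit the min-max normalization's dependence on each
score's observed range. The interpolator cannot extrapolate beyond each
gene's sampled range (by design), and sparsely sampled territory inherits
the nearest samples' profiles. No spatial-autocorrelation-preserving null
models (spin tests) are provided — the association stage tests exactly the
plain Spearman + BH procedure — and real-mode inputs are assumed already
registered to a common space.
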