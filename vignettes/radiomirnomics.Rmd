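---
title: "radiomiR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radiomiR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

radiomiR implements a radiogenomic ("radiomiRNomic") analysis chain for
breast DCE-MRI: quantitative phenotyping of an enhancing lesion on a
subtraction image, correlation of those imaging features (IFs) with miRNA
expression measured on the same patients, and evaluation of small
miRNA/IF signatures as classifiers of the Luminal A intrinsic subtype
against the pooled Luminal B / HER2+ / Basal subtypes. Because matched
public imaging + miRNA cohorts cannot be shipped, the package carries a
first-class synthetic cohort generator whose defaults reproduce the shape
of the cohorts this design targets: a discovery set of 37 subjects
(24 Luminal A, 4 Luminal B, 3 HER2+, 6 Basal) with paired volumes and
expression, an imaging-only validation shape of 27 subjects (15/5/3/4),
and an expression-only validation shape of 331 samples (155/89/42/45).

The stages, each exposed as plain functions and orchestrated by
`run_pipeline()`:

1. **simulate** — `generate_cohort()`: paired pre/post-contrast volumes
   with a single ellipsoidal enhancing lesion per subject plus a miRNA
   expression matrix with planted IF correlations and subtype shifts.
2. **segment** — `region_grow_segment()`: seeded 26-connected region
   growing on the subtraction image `post - pre`.
3. **extract** — `extract_all()`: a 57-feature panel per lesion
   (16 intensity-histogram, 9 shape, 21 gray-level co-occurrence,
   11 gray-level run-length features).
4. **reduce** — `reduce_features()`: Spearman correlation clustering with
   coefficient-of-variation representatives, or the fixed 16-feature
   association panel (`panel = "table5"`).
5. **associate** — `pearson_map()` / `filter_significant()`: Pearson r
   with two-sided t-test p-values per (IF, miRNA) pair; strict `p < 0.05`
   retention, with a separately reported borderline band
   (`0.05 <= p < 0.10`) that is never retained.
6. **evaluate** — `evaluate_signature()` / `enumerate_signatures()`:
   radial-kernel SVM over an exhaustive `cost x gamma` grid, Monte Carlo
   60/40 cross-validation, and ranking of single, pair, and triple
   signatures by mean test AUC.

## The lesion simulator

Each subject draws ellipsoid semi-axes from subtype-specific means
(`lesion_semiaxes_mm` ± `semiaxes_spread_mm`), centers the lesion on the
default 48³ grid of 1 mm isotropic voxels, and builds the subtraction
signal as

```
signal = enhancement_amplitude + noise_sd * texture   (inside the lesion)
signal = noise_sd * white noise                        (outside)
```

The in-lesion *texture* is a Gaussian random field: white noise smoothed
with a separable isotropic Gaussian kernel whose standard deviation is
`texture_corr_length_mm` (in voxels via the grid spacing), standardized
to zero mean / unit variance over the lesion. One parameter therefore
controls run-length and co-occurrence regularity: longer correlation
length gives longer equal-level runs (smaller short-run emphasis) and
tighter co-occurrence diagonals. Histogram skewness is controlled by a
power transform applied to the min-shifted (positive) field — a *signed*
power of a symmetric field would stay symmetric, so the transform acts on
the positive shifted field with exponent `1 + skew` (right tilt) or
`1 / (1 - skew)` (left tilt) and is re-standardized. The pre-contrast
volume is a constant 100-unit tissue baseline plus independent noise;
`post = pre + signal`, so the noiseless limit reproduces the enhancement
amplitude exactly inside the truth mask.

Default subtype phenotypes (chosen once as a plausible aggressiveness
ordering; they are knobs, not estimates): Luminal A lesions are smallest
(7/6/6 mm semi-axes), weakest enhancing (120 units), smoothest
(3 mm correlation length, skew 0.3, noise 30); Basal lesions are largest
(10/9/8 mm), strongest (180), most heterogeneous (1.5 mm, skew 0.9,
noise 45), with Luminal B and HER2+ in between. Increasing the
enhancement-amplitude gap between subtypes monotonically increases
downstream single-feature classification AUC, which is the generator's
main validity check.

## The expression simulator and the reporting scale

A linked miRNA with target correlation `r` to feature `f` is built on a
standardized scale as `r * standardize(f) + sqrt(1 - r^2) * noise`;
unlinked miRNAs are independent noise. Subtype mean shifts are added on
this standardized (log-like) scale in within-subtype SD units. The
reported matrix is `center + z` with `center = 8`, i.e. a positive
affine image of the standardized values resembling log2-normalized
counts. An exponential reporting scale was deliberately *not* used: a
monotone but nonlinear map attenuates Pearson correlations (for a
log-normal scale factor `a`, `cor(e^{aZ}, Z) = a / sqrt(e^{a^2} - 1)`),
which would corrupt the planted correlation strengths the association
stage is tested against; an affine map preserves them exactly.

Planted correlation defaults follow the associations the pipeline is
meant to recover (run-length, histogram and volume features each linked
to one named miRNA) at `target_r = 0.6` — the literature this design
derives from reports only p-values, not effect sizes, so 0.6 is a
package choice: strong enough that a 37-sample discovery cohort detects
it with analytic power ≈ 0.97 at alpha 0.05, weak enough that detection
is not trivial. Subtype shifts default to miR-99a up in Luminal A and
miR-135b / miR-155 up in the other subtypes, in 1 SD units.

What the generator does **not** emulate: pharmacokinetic enhancement
curves, multi-lesion subjects, non-ellipsoidal margins (spiculation),
scanner/site batch effects, count-like expression noise (mean–variance
coupling), or correlated miRNA co-regulation modules. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under the designed data-generating process, not that the
pipeline's biological conclusions transfer to real cohorts.

## Segmentation

Region growing uses 26-connectivity (the common default for blob-like
enhancing masses) from an explicit seed voxel. The inclusion threshold
is `grow_fraction` (default 0.5) times the mean intensity of the seed's
3×3×3 neighborhood; the mask is the seed's 26-connected component among
voxels at or above that threshold, optionally capped at `max_voxels`
(flagged and warned when hit). Because the threshold is recomputed from
the seed neighborhood, adding a constant to the whole volume moves the
threshold by `grow_fraction * c` rather than leaving it fixed — the
documented and tested behavior. Voxel indices are 1-based `(i, j, k)`,
the R convention; world coordinates are `origin + (index - 1) * spacing`.
Seeds are user-supplied (the pipeline uses the grid center, where the
simulator places the lesion); no claim is made of replicating any
manually edited reference masks.

## The 57-feature panel

Intensities are discretized into 32 equal-width bins over the in-mask
`[min, max]` (flag-controlled; the top edge maps into the top bin; a
constant region collapses to one level and is flagged). Choices where
the field's conventions vary:

* Histogram moments are population moments; kurtosis is the non-excess
  Pearson form (`m4/m2^2`, 3 for a Gaussian). Entropy (base 2),
  uniformity and gray-level count use the discretized histogram; all
  other first-order features use raw intensities.
* Shape: volume is voxel count × voxel volume; surface area is the total
  area of exposed voxel faces. This overestimates smooth surfaces by a
  factor approaching 1.5 (so digitized-ball sphericity converges to
  exactly 2/3, a property the tests pin down by brute-force
  voxelization); it is used consistently, so between-lesion contrasts
  remain meaningful. Surface-to-volume ratio is reported in 1/cm, volume
  additionally in cm³, the maximum 3D diameter as the largest pairwise
  distance between surface-voxel centers in mm.
* Texture: the 21 Haralick-style co-occurrence features and 11
  Galloway-style run-length features are computed per displacement for
  the 13 unique distance-1 lattice directions and averaged at the
  feature level; directions with an empty co-occurrence matrix or a
  degenerate marginal (correlation, imc1, imc2 → NaN) are excluded from
  that feature's mean. Displacements are in voxel steps; anisotropic
  spacing affects only shape features. The "32 textural features" split
  of 21 + 11 is a package decision consistent with the named members of
  the association panel (correlation, variance, cluster prominence,
  cluster tendency, sum average; LRE, SRE, RP, LRLGLE, LRHGLE).
* `sum_variance` is the variance of the sum distribution about sum
  average (not about sum entropy, an older variant), and
  `difference_variance` the variance of the difference distribution
  about its mean.

Every co-occurrence and run-length quantity is verified against
independent brute-force enumeration (explicit pair loops, explicit run
walks, direct formula evaluation) on random 6³ regions at a mixed
relative/absolute tolerance of 1e-10 on the features' natural scale.

## Redundancy reduction

Spearman correlations (average ranks, pairwise-complete) over all 57
features; features are clustered as the connected components of the
graph with an edge where `|rho| >= 0.80`. The threshold is unstated in
the source design and 0.80 is common radiomics practice; it is exposed
everywhere and the report makes the resulting panel size auditable.
Connected components are the simplest rule consistent with collapsing
"clusters of highly correlated features"; clustering runs across all
feature groups, with group membership recoverable from the registry.
Each cluster is represented by its member with the largest coefficient
of variation `sd/|mean|`; zero-mean members are CV-unstable (`Inf`),
flagged, and skipped unless the whole cluster is flagged; ties break to
registry order. A fixed 16-feature panel (`panel_16()`) is available as
a preset so downstream stages can run the canonical association panel
directly.

## Association

Pearson r with two-sided p from `t = r sqrt(n-2)/sqrt(1-r^2)` on `n - 2`
df; `|r| = 1` reports `p = 0`; pairs with fewer than 3 complete
observations or a constant vector are undefined with a reason code.
Retention is strictly `p < alpha` (default 0.05) with no multiplicity
correction — matching the protocol this design follows — but a
Benjamini–Hochberg q column is attached for information, since roughly
16 × 10 pairs are tested per subtype. The borderline band exists because
narrative reports of `p = 0.06` pairs as "correlated" are common; the
strict rule wins for retention. Maps are computed within subtype strata
by default (the convention behind per-subtype association heatmaps),
with a pooled mode available; within-subtype n can be as small as 3, so
per-stratum significance at that size effectively requires `|r| > 0.997`.

## Signature evaluation

Luminal A is the positive class. Each Monte Carlo repeat draws a
stratified 60/40 split (train size `floor(0.6 n)`, per-class floors with
the remainder to the larger class — at n = 37 this is 22/15), z-scores
each signature column with training-set statistics only, grid-searches a
radial SVM over `cost in {0.1, 1, 10, 100} x gamma in {0.5, 1, 2}`
(exactly 12 pairs) by stratified 5-fold inner cross-validated AUC on the
training rows, refits the winner, scores the held-out rows, and records
the Mann–Whitney AUC (ties counted ½). Defaults that the source protocol
leaves open, fixed here: 100 repeats; stratified splitting (the 24-vs-13
imbalance makes unstratified splits frequently degenerate); inner model
selection by AUC (the alternative, error rate, is less appropriate under
imbalance); ties toward smaller cost then smaller gamma; scores oriented
structurally toward the positive class with no post-hoc flipping, so
AUC < 0.5 is reported as-is. `enumerate_signatures()` evaluates all
singles, all miRNA × IF pairs, and all triples containing at least one
miRNA, sharing the split sequence within a run so signature comparisons
are paired, and ranks by mean AUC with a deterministic name tie-break.

Two finite-sample facts matter when reading these numbers at n = 37.
First, the per-cohort mean AUC of a null signature is unbiased across
cohorts (measured 0.496 over 2000 protocol draws) but varies by ±0.1
between cohorts, so null-calibration checks average over replicate
draws or permutations. Second, adding a feature costs the SVM real
performance at this sample size: with a 1 SD class shift in each of two
features, the theoretical pair-over-single AUC margin of ~0.08 is
largely consumed by the added dimension, and the measured expected
margin is only ~0.02. The combination analyses therefore operate at
1.25 SD per modality (population AUC ~0.81 single, ~0.89 pair — the
magnitude regime where combining modalities demonstrably helps), chosen
by a power scan over {0.8, 1.0, 1.25} SD and fixed.

## Reproducibility and problem sizes

One master seed drives everything; per-sample and per-repeat seeds are
derived by a stable integer hash, so cohorts are bit-identical under the
same seed and subsetting one sample does not shift another's data. The
test suite and the acceptance script size their simulations to run on a
single CPU in minutes: 48³ default grids, 37-sample cohorts, 1000-pair
null calibrations, 500-pair power checks, 50-replicate redundancy
recovery, and signature evaluations of 40–100 Monte Carlo repeats —
sizes at which every calibration band asserted in the tests was
verified to hold with margin.

## Known limitations

* Numeric parity with any specific historical radiomics build is not a
  goal; definitions are standard and oracle-tested, but binning or
  aggregation conventions elsewhere may differ.
* The exposed-face surface area overestimates smooth surfaces (factor
  → 1.5); sphericity-family features are internally consistent but not
  comparable to mesh-based implementations.
* No DICOM ingestion, motion/bias-field correction, kinetic modelling,
  wavelet/filtered features, size-zone matrices, or survival analysis.
* The SVM protocol is faithful to its source at n = 37, where single
  Monte Carlo AUC estimates carry sd ≈ 0.1–0.15 per repeat; mean AUCs
  from small cohorts should be read with the replicate-variability
  caveats above.
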