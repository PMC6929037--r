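# radiomiR

Radiomic–miRNA association and signature evaluation for breast DCE-MRI.

## The problem

Intrinsic breast cancer subtypes (Luminal A, Luminal B, HER2+, Basal)
differ in prognosis, and Luminal A — the low-risk class — is the one a
clinician most wants to separate from the rest before surgery. Two
non-invasive data sources speak to the subtype: the phenotype of the
enhancing lesion on dynamic contrast-enhanced MRI, quantified by
*radiomic* imaging features (IFs), and circulating/tissue *miRNA*
expression. radiomiR implements the full radiogenomic
("radiomiRNomic") analysis connecting the two:

1. build the **subtraction image** (first post-contrast minus
   pre-contrast) and segment the lesion by seeded **region growing**;
2. extract a **57-feature radiomic panel** — 16 intensity-histogram
   features, 9 shape features, and 32 texture features from the
   gray-level co-occurrence matrix (GLCM, 21 Haralick-style) and
   gray-level run-length matrix (GLRLM, 11 Galloway-style), averaged
   over the 13 unique 3D lattice directions;
3. collapse redundant features by **Spearman correlation clustering**
   (connected components at |ρ| ≥ 0.8) keeping the member with the
   largest coefficient of variation, or use the fixed 16-feature
   association panel;
4. map **Pearson correlations** between IFs and miRNA expression with
   two-sided t-test p-values (`t = r√(n−2)/√(1−r²)`), retaining pairs
   with p < 0.05;
5. rank single, pair, and triple miRNA/IF **signatures** for
   Luminal A vs. the rest with a radial-kernel SVM (grid
   `cost ∈ {0.1, 1, 10, 100} × γ ∈ {0.5, 1, 2}`, inner 5-fold CV),
   **Monte Carlo 60/40 cross-validation**, and the Mann–Whitney **AUC**
   (the probability a random Luminal A sample outscores a random
   non-Luminal-A sample).

Matched public imaging+miRNA cohorts cannot be redistributed, so the
package ships a first-class synthetic cohort generator
(`generate_cohort()`) whose defaults reproduce the target study shapes:
37 paired samples (24 Luminal A + 13 other), an imaging-only 27-sample
validation shape, and an expression-only 331-sample (155 + 176) shape,
with subtype-dependent lesion phenotypes and planted miRNA–IF
correlations of known strength. See the methods vignette
(`vignettes/radiomirnomics.Rmd`) for the models and every design
decision.

## Worked example

```r
library(radiomiR)

# a 37-sample discovery-style cohort: volumes + truth masks + expression
cohort <- generate_cohort(cohort_config("brca1"), seed = 42)
cohort
#> <SyntheticCohort> preset brca1: 37 samples (24 LuminalA, 4 LuminalB,
#>   3 HER2, 6 Basal), 20 miRNAs

# the fixed 16-feature association panel
red <- reduce_features(cohort$features, panel = "table5")
red
#> <RedundancyReport> 16 features -> 16 representatives (fixed 16-feature panel)

# per-subtype Pearson map, strict p < 0.05 retention
map <- pearson_map(red$reduced, cohort$expression, stratify = cohort$labels)
hits <- filter_significant(map, alpha = 0.05)$retained
head(hits[hits$stratum == "LuminalA", c("feature", "mirna", "r", "p", "n")])
#>                  feature   mirna      r        p  n
#>            glcm_variance miR-155  0.669 0.000348 24
#>    glcm_cluster_tendency miR-155  0.665 0.000396 24
#>  glcm_cluster_prominence miR-155  0.661 0.000434 24
#>                   median miR-452 -0.648 0.000609 24
#>                 skewness miR-452  0.638 0.000795 24

# Monte Carlo CV of a combined miRNA + imaging-feature signature
combined <- cbind(red$reduced,
                  as.data.frame(t(cohort$expression[, red$reduced$sample_id])))
evaluate_signature(c("miR-135b", "glrlm_sre"), combined,
                   cohort$labels$subtype, cv_config(n_repeats = 100, seed = 7))
#> <CVResult> miR-135b + glrlm_sre: mean AUC 0.841 (sd 0.082, 100 repeats, n = 37)
```

The retained pairs are the generator's planted structure surfacing back
(miR-155 was planted against GLCM variance, miR-452 against skewness;
cluster tendency/prominence travel with variance), and the combined
signature's mean AUC of 0.84 reflects the miR-135b subtype shift plus
the run-length texture contrast between subtypes.

The full pipeline is one call — `run_pipeline(pipeline_config(...))` —
which writes `features.csv` (57 columns), `reduced.csv`,
`associations.csv`, `ranking.csv` and a JSON run manifest;
`make_demo(dir)` materializes a ready-to-run workspace. A thin
command-line wrapper with subcommands
(`simulate / segment / extract / reduce / associate / evaluate /
run-all / demo`) is installed at `inst/cli/radiomir.R`.

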