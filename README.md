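# adcphenotype

Radiomic phenotyping of kidney apparent diffusion coefficient (ADC) maps in
chronic kidney disease (CKD).

Diffusion-weighted MRI (DWI) probes water mobility in tissue; in the kidney
cortex, restricted diffusion accompanies interstitial fibrosis, the hallmark
of progressive CKD. A voxelwise ADC map is obtained from the mono-exponential
signal model

    S(b) = S0 · exp(−b · ADC)

fitted over several diffusion weightings *b* (s/mm²). Mean cortical ADC alone
discriminates CKD poorly; this package instead characterizes the *texture* of
the ADC map with 54 radiomic features — 15 first-order (histogram) statistics,
23 gray level co-occurrence matrix (GLCM) features and 16 gray level run
length matrix (GLRLM) features, computed under fixed-bin-width discretization
(bin width 4×10⁻⁵ over 0–4×10⁻³ mm²/s, 100 gray levels) — and feeds them into:

- **descriptive statistics**: Spearman correlation maps with strong / moderate
  / weak categories, and normality-routed two-group comparisons
  (Shapiro–Wilk → Welch *t* or Wilcoxon rank-sum);
- **unsupervised phenotyping**: Z-score normalization, hierarchical clustering
  of subjects under correlation distance (1 − Pearson *r*), and selection of
  the cluster number by a full-covariance Gaussian-mixture BIC scan over 1–10
  components;
- **supervised classification**: forward-selection logistic regression that
  adds features while the in-sample AUC-ROC improves, for CKD vs healthy and
  for rapid vs non-rapid progression (annual eGFR slope ≤ −3 mL/min/1.73 m²),
  with radiomics-only, clinical-only and combined candidate pools.

Because kidney DWI studies rarely share patient images, the package ships a
first-class synthetic-data module: `generate_cohort()` simulates a 10 healthy
+ 30 CKD cohort with group-specific cortical ADC level, dispersion and
spatial texture, a realistic acquisition protocol (b = 200–1000 s/mm², five
averaged repeats, five coronal slices), and clinical covariates (eGFR, BMI,
blood pressure, proteinuria, eGFR-slope mixture with 23% rapid progressors).
Every downstream stage is therefore testable end to end without any download.
It is intended for imaging methodologists and nephrology researchers
prototyping radiomics pipelines on quantitative renal MRI.

## Worked example

```r
library(adcphenotype)

result <- run_pipeline(cohort_config())   # 10 healthy + 30 CKD, seed 7
result
#> <adc_pipeline_result> 40 subjects; best k = 2; CKD-model AUC 1.000

result$phenotype$cluster_comparison$cluster_summary
#> # A tibble: 2 × 5
#>   .cluster     n n_ckd ckd_fraction mean_egfr
#>   <fct>    <int> <int>        <dbl>     <dbl>
#> 1 1           30    30            1      53.2
#> 2 2           10     0            0      84.7

library(dplyr)
result$features |>
  group_by(group) |>
  summarise(CoV = median(CoV), Mean = median(Mean))
#> # A tibble: 2 × 3
#>   group     CoV    Mean
#> 1 ckd     0.244 0.00175
#> 2 healthy 0.174 0.00183
```

The default synthetic cohort reproduces the intended structure: the GMM-BIC
scan bottoms out at two clusters, the two-cluster cut isolates an all-CKD
phenotype with lower eGFR, and the CKD group shows higher ADC dispersion
(CoV) at a slightly lower median ADC (mm²/s). The 54-feature Spearman map
evaluates 1431 distinct pairs. Note that classification AUCs are *in-sample*
(selection and evaluation on the same 40 subjects, as is common in small
feasibility cohorts) and therefore optimistic; on cleanly separable synthetic
data they saturate at 1.0.

Individual stages compose with the pipe as well:

```r
cohort   <- generate_cohort(cohort_config(seed = 11))
features <- cohort_features(cohort)
tree     <- features |> zscore_normalize() |> hierarchical_cluster()
gmm      <- features |> zscore_normalize() |> gmm_bic_select(seed = 1)
autoplot(gmm)                      # BIC curve
tidy(spearman_map(features, feature_registry()$feature))
```

A command-line entry point for whole runs lives at
`inst/cli/adc-radiomics.R` (`Rscript adc-radiomics.R --config cohort.yaml
--out DIR`).

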