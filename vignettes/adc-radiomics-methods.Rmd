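---
title: "Methods: radiomic phenotyping of kidney ADC maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic phenotyping of kidney ADC maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`adcphenotype`, in the spirit of the methods sections of mature analysis
packages: what is computed, under which assumptions, and where the genuinely
open choices were settled.

## Signal model and ADC fitting

Diffusion-weighted signal is modelled as mono-exponential decay,
$S(b) = S_0 e^{-b \cdot \mathrm{ADC}}$, with $b$ in s/mm² and ADC in mm²/s.
`fit_adc_map()` estimates ADC per voxel by **unweighted ordinary least
squares of $\ln S$ on $b$**: the fit is closed-form, deterministic, and the
standard approach for mono-exponential ADC mapping. The protocol starts at
$b = 200$ s/mm² (no $b = 0$ image), so $S_0$ is an extrapolated intercept,
not a measured image. IVIM/bi-exponential and kurtosis models are out of
scope, as is motion/eddy-current correction; input b-value volumes are
assumed co-registered (registration is upstream preprocessing, and the
synthetic data are natively aligned).

Quality control follows exclusion rather than imputation: a voxel with any
non-positive signal (logarithm undefined) or a negative fitted ADC is
removed from the output mask and counted in a message; fitted values above
the physical ceiling of $4\times10^{-3}$ mm²/s are retained but flagged. A
slope within $10^{-12}$ of zero is clamped to ADC $= 0$ so constant signal is
handled exactly.

## Discretization and the 54 features

ADC values are discretized with a **constant bin width of
$4\times10^{-5}$ mm²/s over the fixed range 0–$4\times10^{-3}$ mm²/s**
(100 gray levels): `level = floor((adc − min)/width) + 1`, with out-of-range
values clamped into the boundary bins (the range defines the histogram
support). A fixed absolute scale — rather than per-subject min–max — makes
gray levels comparable across subjects.

The feature set is exactly 54 named features: 15 first-order, 23 GLCM and 16
GLRLM. Conventions that the literature leaves open are explicit arguments
with these defaults:

- **Entropy base**: log₂ (bits), the common radiomics convention, for all
  entropies (first-order, GLCM joint/difference/sum, GLRLM run entropy).
- **Kurtosis**: Pearson (non-excess). Reported cortical kurtosis values in
  the 1–4 range are consistent with either convention; the excess variant is
  available via `kurtosis = "excess"`.
- **Variance**: population (ddof 0), with `variance_ddof = 1` available.
- **Quantile features** (0.01 … 0.99) are computed on the *raw* ADC values
  with linear interpolation, not on the discretized histogram, so they
  retain sub-bin resolution in mm²/s.
- **Normalized inverse-difference features** divide by the full fixed
  $N_g = 100$, not the occupied level range: fixed-bin-width discretization
  defines an absolute scale.

Texture is computed **in 2-D within each slice** at distance 1 along the
four planar directions (0°, 45°, 90°, 135°), with pair/run counts merged
over slices per direction and features averaged over the four directions.
At 5 mm slice thickness versus ~2–3 mm in-plane resolution, through-slice
texture would mix scales; the in-plane choice also keeps run percentage in
(0, 1], matching the magnitudes expected for cortical ROIs (~0.93–0.96).
GLCMs are symmetric (both orderings of each pair counted) and normalized to
sum 1; GLRLM runs are maximal, break at mask boundaries, and satisfy the
pixel-conservation identity $\sum_j j \, R(i,j) = N_p$ per direction.
Degenerate inputs are flagged, never silently zeroed: a constant ROI leaves
skewness, kurtosis and GLCM correlation undefined (`NA`), and
`extract_features()` raises an error naming any non-finite feature.

Left and right kidney feature vectors are combined by elementwise averaging
into one representative vector per subject; the Spearman correlation between
the two sides is attached as a QC value (near 1 on synthetic data, ~0.99,
supporting the combination).

## The synthetic cohort

`generate_cohort()` emulates a feasibility study of 10 healthy volunteers
and 30 participants with mild-to-moderate CKD. Per kidney it draws a
C-shaped elliptical cortical band (~1,500 voxels over 5 coronal slices by
default; the ROI size is a config value, since real cortical ROI voxel
counts vary with drawing style), fills it with a Gaussian random field
(white noise smoothed per slice at the group's correlation length, then
affinely rescaled so the in-mask mean and population SD hit their targets
exactly), synthesizes DWI at b = 200, 300, 500, 700, 1000 s/mm² with
additive zero-mean Gaussian noise per repeat, and averages five repeats.
Averaged multi-repeat magnitude data at the simulated SNR (S0 = 800, noise
SD = 15 per repeat) is well approximated by Gaussian noise, so no Rician
model is used.

Group parameters are fixed once, at values representative of published
cortical ADC statistics: healthy ADC $1.83\times10^{-3} \pm 3.1\times10^{-4}$
mm²/s with correlation length 3 voxels; CKD $1.75\times10^{-3} \pm
4.2\times10^{-4}$ with correlation length 1.5. CKD thus differs in both
dispersion (CoV 0.24 vs 0.17) and texture coarseness — the shorter
correlation length raises contrast-type features — because observed CKD
differences span both variance-type and contrast-type features. Clinical
covariates are group-conditional normals (eGFR 88.6 ± 12.6 vs 51.5 ± 12.2
mL/min/1.73 m²; BMI 25.8 ± 2.7 vs 32.4 ± 7.5 kg/m²; age 58.1 ± 9.4 vs
65.3 ± 9.6 y), with blood pressure, glucose and proteinuria collected only
for CKD subjects (healthy values missing, as in typical research cohorts).
Proteinuria is zero-inflated log-normal (25% exact zeros — making 0 g/day
the modal value — meanlog −1.7, sdlog 1.1, rounded to 0.01 g/day) with 13%
of values missing.

The annual eGFR slope of CKD subjects is a **two-component truncated
mixture**: with probability 0.23 the subject is a rapid progressor and the
slope is drawn from $N(-5.27, 2.61^2)$ truncated to $\le -3$; otherwise from
$N(0.92, 2.57^2)$ truncated to $> -3$. Truncating at the classification
threshold guarantees that generated labels and `classify_rapid()` (slope
$\le -3$; the threshold itself counts as rapid, resolving the "loss ≥ 3" vs
"loss > 3" ambiguity toward the definition) can never disagree. The
truncated mixture mean (≈ −0.44) sits close to the untruncated arithmetic
−0.50, matching reported cohort-level slopes around −0.5 ± 3.7.

What the generator does **not** model: anatomy (the ROI is a stylized band),
respiratory motion, scanner artifacts, Rician bias, cysts, and any
dependence of texture on clinical covariates beyond group membership.
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under controlled effect sizes — not clinical performance on real
MRI.

A single config seed fans out to per-subject and per-stage child seeds
through a label-keyed mixing function (`child_seed()`), so cohorts are
bit-reproducible and stages are individually reproducible regardless of how
many draws other stages consume.

## Descriptive statistics

`spearman_map()` computes pairwise Spearman ρ with two-sided p-values
(t-approximation; exact p is unavailable under ties) on pairwise-complete
observations. Significant pairs (p < 0.05, no multiple-testing correction —
deliberately mirroring the exploratory single-threshold convention of small
feasibility studies) are categorized by |ρ|: strong [0.7, 1], moderate
[0.3, 0.7), weak [0, 0.3), with closed lower bounds, signed pos/neg. Counts
are over distinct unordered pairs (1431 for 54 features).

`group_compare()` routes deterministically on normality: Shapiro–Wilk at
α = 0.05 per group (the routing test is a package choice; constant groups
count as non-normal); both pass → Welch *t*-test with mean ± SD summaries,
otherwise Wilcoxon rank-sum with median (IQR). Welch is preferred over the
pooled-variance *t* as the safer default under unequal variances. Missing
clinical values are excluded pairwise.

`ckd_epi_egfr()` implements the 2009 CKD-EPI creatinine equation (sex-specific
knot κ and exponent α, age factor 0.993^age, 1.018 female factor; no race
coefficient), and `egfr_slope()` is the per-subject OLS slope of eGFR on time.

## Phenotyping

Features are Z-scored per column ($Z = (x - \bar{x})/\mathrm{SD}$, population
SD by default, matching the convention of the common clustering tools;
sample SD available). Subjects are clustered agglomeratively under
**correlation distance** $1 - r$ (0 = identical profile, 2 = opposite) with
**average linkage** — the standard pairing with correlation distances; the
linkage is configurable (complete, single, Ward). The two-phenotype labels
come from cutting at the final merge (top split), the natural reading of an
"upper half / lower half" dendrogram description. Feature columns are
ordered by the same procedure on the transposed matrix for heat-map export,
and the cluster with the lower mean eGFR is reported as cluster 1.

The number of clusters is selected by fitting full-covariance Gaussian
mixtures for $k = 1\ldots10$ and minimizing
$\mathrm{BIC} = p \ln n - 2 \ln \hat{L}$ with
$p = (k-1) + kd + kd(d+1)/2$. Two safeguards make this well-posed on a
40 × 54 table:

- **Dimensionality**: a full-covariance mixture needs more subjects than
  dimensions, so the mixture is fitted on the top principal components
  capturing ≥ 95% of variance (2–4 components in practice, since radiomic
  features are heavily collinear). The retained count is reported.
- **Degeneracy**: with unequal covariances the mixture likelihood is
  unbounded — EM can shrink one component onto a few nearly coincident
  points. EM runs with a k-means initialization, 10 restarts, and an
  eigenvalue floor of $10^{-6}$ on component covariances; a *converged*
  solution whose covariance sits at the floor, or with fewer effective
  members than dimensions in some component, is rejected as degenerate
  rather than scored. If no restart survives for some $k$, that BIC entry is
  flagged `NA` with a warning. BIC ties resolve toward the smaller $k$.

The EM implementation is validated in the test suite against mclust (same
selected $k$, log-likelihood agreement) on well-conditioned data.

## Classification

`forward_select_logistic()` starts from the intercept-only model and, at
each step, refits maximum-likelihood logistic regression for every remaining
candidate added to the current set, adding the candidate with the largest
**in-sample AUC-ROC** if it improves on the current AUC by more than
$10^{-6}$; ties resolve toward the earlier candidate in canonical feature
order. Selection and evaluation use the same subjects — deliberately, to
mirror the common procedure on small feasibility cohorts — so the reported
AUC is optimistic and is documented as such rather than "fixed";
cross-validated selection can be layered on by the user. Features are
standardized before fitting for numerical stability. Perfect separation
(frequent with 54 candidates and 40 subjects) is detected by non-convergence
or an implausible standardized slope (|β| > 15) and handled by refitting
with a small ridge penalty (λ = 10⁻⁴), recorded in the trace.
Sensitivity/specificity are reported at the 0.5 probability threshold (the
operating point is configurable since conventions differ). AUC is the exact
Mann–Whitney pairwise probability with ties counted ½; missing proteinuria
is mode-imputed (ties toward the smaller value) before model fitting.

`build_progression_models()` fits the three standard pools among CKD
subjects — 54 radiomic features; clinical (sex, age, SBP, DBP, eGFR, BMI,
proteinuria, glucose); and their union — for rapid vs non-rapid progression.

## Problem sizes and reproducibility

The test suite exercises full-size cohorts (grids of 5 × 64 × 128,
~1,500-voxel ROIs) for the single-cohort checks, and reduced grids
(4 × 32 × 64, ~400-voxel ROIs) for the 50-seed recovery suites; the reduced
grids keep every *statistical* parameter (group means, SDs, correlation
lengths, noise, sample sizes) at its default, scaling only the image
dimensions. Oracle tests compare the texture matrices against exhaustive
enumeration on all 512 binary 3 × 3 images and the 39 texture features
against independent literal-formula implementations at $10^{-12}$ relative
tolerance.

## Known limitations

Synthetic kidneys are stylized bands, not anatomy; Rician noise, motion and
partial-volume effects are absent. In-sample selection AUCs do not estimate
generalization. The GLCM/GLRLM aggregation (2-D, distance 1, four
directions, merge-then-average) is one of several defensible conventions;
alternatives change feature values and should be held fixed within a study.
With ~40 subjects the BIC curve near its minimum is shallow, so the selected
cluster number can move between 2 and 3 across cohort realizations even when
two phenotypes are planted.
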