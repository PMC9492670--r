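---
title: "Methods: brain age estimation and brain-PAD statistics in brainpad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain age estimation and brain-PAD statistics in brainpad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpad)
```

## The problem

Brain-age models regress chronological age on neuroimaging features in a
healthy population, then apply the trained model to a clinical group. The
signed difference between (bias-corrected) predicted age and chronological
age — the brain-predicted age difference, **brain-PAD**, in years — is used
as a marker of accelerated or decelerated brain aging. `brainpad`
implements this analysis for resting-state functional connectomes collected
across many imaging sites, where the features are the pairwise Pearson
correlations between regional BOLD time series (6670 edges for a
116-region parcellation) and the clinical contrast of interest is a
patient-vs-control difference in mean brain-PAD of a few years against a
within-group SD near 10 years.

The pipeline stages, in order: connectome construction, site
harmonization, control train/hold-out split, stacked ensemble age
regression with out-of-fold discipline, hold-out age-bias correction,
brain-PAD scores, group statistics.

## Connectome features

`pearson_fc()` correlates every pair of regional time series;
`vectorize_upper()` takes the strictly upper triangle in **row-major order**
(row < column), the single canonical edge ordering used everywhere
(`edge_names()` prints it; `devectorize()` inverts it). No Fisher r-to-z
transform is applied: downstream standardization operates on raw
correlations, and a z-transform would only reparametrize the
approximately linear edge–age trends the model exploits. Zero-variance
regions (flat signals do occur in pooled multi-site data) zero out their
edges with a warning by default; `strict = TRUE` rejects instead.

**Standardization scope.** "Z-score the connectivity of each subject" is
read literally: `harmonize_zscore()` standardizes each subject's own 6670
edges to mean 0, sample SD 1 (divisor n−1 throughout the package). This
removes subject/site-level global offsets in connectivity strength but not
per-edge site effects. The per-site-per-edge alternative is available as
`harmonize_zscore_site()`, and an empirical-Bayes location/scale model as
`harmonize_combat()`.

## ComBat-style harmonization

`harmonize_combat()` fits, per edge, a location/scale model with site
effects and a protected biological design (age by default; add `"age2"`,
`sex`, diagnosis as needed), standardizes residuals, shrinks the
per-(site, edge) location shifts toward a normal prior and the squared
scales toward an inverse-gamma prior (method-of-moments hyperparameters,
iterative conditional posterior), and reassembles the data with the
protected effects restored. Two numerical choices matter:

* Per-site scale estimates use the MLE divisor (n_s rather than n_s − 1),
  matching the pooled-variance divisor. This makes the **no-shrinkage mode
  exactly idempotent**: once site location/scale are removed, refitting
  estimates zero shift and unit scale and a second pass is a no-op to
  floating precision. With shrinkage, idempotence is only approximate by
  design — empirical Bayes deliberately leaves O(sampling noise) residual
  site effects.
* A site with one subject makes the scale inestimable and is rejected, as
  is a protected covariate that is constant within every site (fully
  confounded with site).

`harmonization_report()` summarizes per-edge one-way site-association F
statistics before/after, and optionally refits a quick ridge age model
under each table to compare downstream MAE — the basis for choosing
between Z-score and ComBat on a given data set.

## The stacked age model

Three base learners are fitted on the training controls with 5-fold
cross-validation, folds stratified by age decile (`make_folds()`):

| learner | objective (intercept unpenalized) | default |
|---|---|---|
| elastic net | (1/2n)·RSS + λ(α‖β‖₁ + (1−α)/2‖β‖₂²) | λ = 1, α = 0.5 |
| ridge | RSS + λ‖β‖₂² | λ = 1 |
| Bayesian ridge | evidence maximization, Gamma hyperpriors | all 10⁻⁶ |

"Default parameters" is meaningless across ecosystems, so these are pinned
numerically (they are the conventional defaults of the common machine
learning stack this analysis style comes from). The elastic net is
delegated to `glmnet` (identical objective with `standardize = FALSE`);
ridge is a closed-form solve (dual form when p > n); the Bayesian ridge is
a small SVD-based evidence-maximization loop, since no installed R package
provides that estimator.

**Out-of-fold discipline.** Every subject's out-of-fold (OOF) prediction
comes from the one fold model that excluded them; the stacking
meta-learner — ordinary least squares with intercept, the canonical linear
stacking combiner — is fitted *only* on the OOF prediction columns
(`fit_stacking()`). Rank-deficient OOF matrices (e.g. two identical base
learners) fall back to the minimum-norm least-squares solution with a
warning. At test time each learner's K fold models are averaged and the
meta weights applied; `per_fold = TRUE` instead keeps the K per-fold
predictions, which is how the fold-wise mean ± SD metric tables are
produced. `evaluate()` reports MAE (years), MSE (years²) and R².

Feature importance is the fold-averaged absolute coefficient, normalized
to sum to 1 (ties broken by edge index); for the stacked model the
per-learner importances are combined with weights proportional to the
absolute stacking weights. `edge_age_correlations()` gives the
complementary mass-univariate view: the per-edge Pearson correlation with
age, signed counts, within-sign means ± SD and extreme edges.

## Split, bias correction, brain-PAD

`make_split()` holds out a fraction of controls (default 0.2, matching the
common ~80/20 practice) with two guarantees: every site with ≥ 2 controls
appears in both subsets (largest-remainder allocation of the per-site
hold-out counts), and within each site the hold-out is a systematic sample
along the age ordering with random phase, so the hold-out spans the whole
age range at every site. A single-control site goes to training with a
warning. Patients are never in a control subset.

Brain-age estimators regress toward the mean age, so raw predictions are
biased young for old subjects and vice versa. `fit_bias()` regresses raw
predicted age on chronological age in the **hold-out controls only** (the
set that never touched model fitting), and `apply_bias()` rescales:

corrected = (raw − intercept) / slope,  brain-PAD = corrected − age.

This affine rescaling (rather than residual subtraction, available via the
same slope/intercept if wanted) makes the reported slope and intercept the
operational correction parameters. Two consequences are tested exactly: on
the fitting set, brain-PAD has mean 0 and zero correlation with age
(least-squares orthogonality), and the correction is strictly monotone, so
subject ranking at fixed age is preserved. A |slope| below 10⁻⁶ means the
predictions carry no age signal and the correction is refused. The control
group used in every downstream comparison is the hold-out set only.

## Group statistics

* `compare_groups()`: Welch two-sample t-test by default (the groups'
  SDs genuinely differ in this setting; Student's pooled test behind
  `var_equal = TRUE`), mean difference with 95% CI, Cohen's d with pooled
  SD (Hedges correction off by default).
* `glm_brainpad()`: Gaussian-family identity-link GLM — the only family
  compatible with a years-valued outcome — reporting Wald z statistics,
  normal p-values and Wald CIs in the conventional coefficient-table
  layout. `age2` is computed internally from raw (uncentered) age; a
  centering flag exists. Rows incomplete in the requested terms are
  dropped and counted (complete-case analysis).
* `fdr_adjust()`: Benjamini–Hochberg step-up via `p.adjust`, applied
  across the subgroup battery.
* `spearman_cor()`: rank correlation with average ranks for ties,
  two-sided p via the t approximation.
* `median_split()`: boundary values go to the upper group ("fewer than m"
  vs "at or above m"), matching the clinical convention for covariates
  like education years and illness duration whose medians sit exactly on
  common values (12).

`run_pipeline()` wires the stages together from a single `run_config()`
with one master seed; per-stage seeds are derived by fixed offsets so
stages are independently re-runnable yet globally reproducible. The
machine-readable summary rounds numerics to 8 significant digits before
serialization so identical runs are byte-identical.

## The synthetic cohort generator

Real consortium data of this kind is request-only, so `generate_cohort()`
emulates its structure with known ground truth. Defaults mirror the study
conditions: 1101 controls and 1276 patients over 24 sites, ages uniform on
12–82, 116 regions, and a patient aging offset of +4.43 years with an
additional +2.09 years for the medicated half of patients.

Each edge e of subject i is generated in Fisher-z latent space and mapped
through tanh (so correlations stay in (−1, 1) with no mass at the
boundary):

z_ie = μ_e + β_e·a_i + γ_e·a_i² + shift(site, e) + scale(site, e)·ε_ie

with a_i = age + Δ·patient + Δ_med·medicated + g_i (centered at the
age-range midpoint). The terms and their defaults:

* μ_e ~ N(0.15, 0.25²): baseline edge strengths of realistic magnitude.
* β_e ~ N(0, 0.0015²) per year: linear aging trends of mixed sign. At
  these values the induced edgewise age correlations have within-sign
  means near ±0.07 with roughly half the edges in each sign — the regime
  reported for real connectomes. A quadratic term (`edge_quad_sd`,
  default 0) exists to exercise the GLM's age² covariate.
* `subject_sd` (default 9.5 years): a per-subject latent brain-age
  deviation g_i. This is the irreducible biology — without it, thousands
  of conditionally independent edges would let any ridge-type model
  predict age to ~1 year, which no functional-connectivity model achieves.
  9.5 years puts the corrected brain-PAD SD near 10 years and hold-out MAE
  near 8 years at the 116-region defaults, the reported scale for this
  kind of data.
* `noise_sd` (default 0.35) per-edge measurement noise; `site_shift_sd`
  (0.05) and log-scale `site_scale_sd` (0.1) per-(site, edge) effects —
  exactly the additive/multiplicative structure Z-score and ComBat
  harmonization differ on. No published site-effect magnitudes exist for
  this consortium; these are chosen for testability.

In time-series mode (`n_timepoints > 0`) each subject instead receives a
T×R Gaussian series whose population correlation is the nearest
positive-definite correlation matrix to the subject's edge matrix
(eigenvalue clipping at 10⁻⁶, rescale to unit diagonal —
`nearest_pd_correlation()`, a fixed point on already-PD inputs), sampled
via the Cholesky factor (`series_from_fc()`). T below R+2 warns about
rank-deficient empirical connectomes.

What the generator does **not** emulate: spatial correlation among edges
beyond the shared age/subject factors, head motion and physiological
noise, non-uniform site sample sizes, age-by-site confounding, and
diagnosis-dependent connectivity topology. Passing tests therefore
demonstrate correctness of the estimation machinery under a known
data-generating process, not performance claims about any real cohort.

## Scaled-down benchmarks and problem sizes

The replicate suites (offset recovery, null calibration) run the full
pipeline hundreds of times, so they use cohorts with fewer regions while
preserving the full-scale signal-to-noise: per-edge noise is scaled by
sqrt(n_edges / 6670) at unchanged slopes. Scaling slopes *up* instead
pushes edges into tanh saturation, where the per-subject z-score (whose
denominator grows with |effective age|) visibly attenuates the recovered
offset — the noise-scaling transform stays in the linear regime and is
unbiased. The shipped suites use 16 regions (120 edges) with 1095 controls
+ 500 patients for recovery replicates, 10 regions with 400 + 250 for null
replicates, and the full 116-region, 1101 + 1276 default for the
single-run benchmark; these sizes are the package's own choice of
replicate-vs-cohort resolution.

One caveat the replicate experiments quantify: with 500 patients, 219
hold-out controls and brain-PAD SD ≈ 10 years, the sampling SD of the
estimated group gap is ≈ 0.8 years (the hold-out mean is pinned to zero by
the bias fit, but the fitted bias line re-injects the hold-out sampling
noise into every corrected patient score). Single-replicate gap estimates
at this size are therefore only ±1.5 y (95%) reproducible, whatever the
estimator — a useful reminder when comparing headline brain-PAD gaps
across studies of this size.

## Degenerate inputs and numerical conventions

Sample SD (n−1) everywhere except the ComBat site scales (MLE, see above);
asymmetry tolerance 10⁻¹⁰ for `vectorize_upper()`; constant connectomes,
constant targets, single-subject sites, confounded protected covariates,
|slope| < 10⁻⁶ bias fits, out-of-range p-values and constant covariates
are all rejected with messages rather than propagated as NaN. Elastic-net
coordinate descent uses a 10⁻⁹ convergence threshold; the Bayesian ridge
stops when coefficients move less than 10⁻³ or after 300 iterations.
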