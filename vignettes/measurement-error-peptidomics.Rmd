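---
title: "Measurement-error-aware analysis of MALDI-TOF peptidomic feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-error-aware analysis of MALDI-TOF peptidomic feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepticc)
```

## The problem

MALDI-TOF/MS profiling of urine or serum produces, after peak detection and
alignment, a *feature table*: one intensity per sample per aligned m/z peak
(here 1000–4000 Da). Two properties of these tables complicate biomarker
screening:

1. **Large measurement error.** Even after normalization, intra-assay
   coefficients of variation of 20–30% are common. When an error-prone
   feature is regressed against disease status, the classical-error model
   implies the fitted log-odds coefficient is *attenuated toward zero* by
   (approximately) the reliability of the measurement — the intraclass
   correlation coefficient, ICC = σ²ᵦ / (σ²ᵦ + σ²𝓌), where σ²ᵦ is the
   between-subject and σ²𝓌 the within-subject variance on the log2 scale.
2. **Left-censoring.** Signals below the instrument's signal limit of
   detection (sLOD) are not observed. How the censored cells are filled
   changes every downstream variance estimate, and therefore the ICC that
   drives the bias correction.

`pepticc` implements the full chain: LOD-aware normalization, ICC and
variance-component estimation from replicate designs, a Monte Carlo study
of ICC reliability under censoring, measurement-error-corrected logistic
screening by regression calibration (RCAL) and
simulation-and-extrapolation (SIMEX), diagnostic accuracy metrics, and a
synthetic-data generator that emulates the statistical structure of the
three study types (repeatability, analytical precision, case-control).

## The error model

All variance parameters in the package live on the **log2 intensity
scale**. Additive normal error there is multiplicative (log-normal) error
on the raw scale, which matches the heavily right-skewed distribution of
MALDI-TOF signal intensities. A repeated measurement of subject *i* is

y_ij = x_i + ε_ij,  x_i ~ N(μ, σ²ᵦ),  ε_ij ~ N(0, σ²𝓌),

and the observed intensity is W = 2^y. In the case-control generator,
disease depends on the **true** level x_i through
logit P(D = 1) = α + Σ_f β_f x_if — the classical-error assumption that
both RCAL and SIMEX require. The generator therefore reproduces the
attenuation law E[β̂_naive] ≈ ICC · β_true, which the test suite verifies
by simulation.

## The sLMNLT normalization stack

`slmnlt()` applies, in this order:

1. `substitute_below_lod()` — flag intensities below the sLOD and fill
   them. The sLOD is estimated as `mean(noise) + k·SD(noise)` (`k = 3` by
   default) from noise-region observations. Fill strategies:
   `lod_half` (sLOD/2, the canonical choice), `zero`,
   `richardson_ciampi` (the truncated-normal conditional mean *below* the
   threshold, E(W | W < sLOD)), and `schisterman` (the conditional mean
   *above* it). The conditional means are computed on the log2 scale with
   plug-in normal parameters estimated from each feature's uncensored
   values; a censored-likelihood refinement was considered and left out
   because the plug-in version is transparent, testable, and adequate at
   the censoring fractions of interest.
2. `median_normalize()` — divide each spectrum by its own median so every
   sample has median exactly 1. This removes per-spot total-signal
   variation and is scale-equivariant. For urine, `creatinine_normalize()`
   is the alternative dilution correction.
3. `log2_transform()` — requires strictly positive entries, which the
   `lod_half` and `richardson_ciampi` fills guarantee (the `zero` fill
   deliberately does not; the transform refuses such tables).

The states form a small machine (`raw → lod-adjusted →
median-normalized → log2`) and each step refuses out-of-order input, so a
table can never be normalized twice or log-transformed before filling.

## Variance components and the ICC

`variance_components()` is the classical unbalanced one-way ANOVA
(method-of-moments) estimator: σ̂²𝓌 = MSW, σ̂²ᵦ = (MSB − MSW)/n₀ with
n₀ = (N − Σn²ᵢ/N)/(k − 1). Negative between-subject estimates are clipped
to zero and flagged rather than smoothed away by REML — the clipping makes
the estimator's behaviour explicit and testable, and matches how
reliability is usually reported for these designs. The F-based
(Searle) interval in `icc_confidence_interval()` is exact for balanced
designs and a standard approximation (via n₀) otherwise; simulated
coverage at ICC = 0.5 over a 20-subject × 3-replicate design is within
Monte Carlo error of 95% (the acceptance suite runs 1000 replicates).

`feature_icc()` averages technical spot replicates per serial sample
*before* the subject-level ANOVA: reliability here is a statement about
biological sampling, not spotting, and the two-component summary matches
how such tables are reported. A three-level nested analysis would be the
natural extension and is deliberately out of scope.

`assay_cv()` handles the analytical 5 × 5 precision design (5 runs ×
5 replicates of a pooled specimen) as a nested ANOVA on the *intensity*
scale, reporting intra-assay CV = 100·σ̂_rep/mean and inter-assay
CV = 100·√(σ̂²_run + σ̂²_rep)/mean.

## Monte Carlo study: is the ICC still reliable under censoring?

`simulate_icc_reliability()` crosses a grid of measurement-error variances
(default 0.01–0.64, read as variances; the alternative reading as SDs is a
constructor argument away) with censoring fractions {12.5%, 25%, 50%} and
the four fill strategies. Within each error level the same simulated
datasets are reused across fractions and strategies, so comparisons are
paired. The censoring threshold is placed at the empirical marginal
quantile of each dataset, which fixes the censoring fraction by
construction. The default between-subject variance (0.345) was chosen
once so that the uncensored ICC runs from ≈0.97 at the smallest error
variance down to ≈0.35 at the largest — the regime in which the method is
actually used — and is configurable.

Substitution happens on the log2 analysis scale: `lod_half` fills with
c − 1 (half an intensity is one log2 unit less), `zero` fills with log2 of
unit intensity (0), and the conditional-mean strategies use plug-in
parameters from the uncensored part of each dataset. Results report both
the SE of the mean over replicates (`mc_se`) and the sampling SD of the
estimator (`mc_sd`); bias comparisons between strategies are made on the
`mc_sd` scale, because a fixed substitution bias always exceeds a
mean-SE band once enough replicates are run, while the scientifically
relevant question is whether the bias is small relative to the
estimator's own variability.

**Known limitation.** At near-zero measurement error (σ²ε = 0.01) the
LOD/2 fill sits ≈0.7 log2 units below the truncated-normal conditional
mean while the total SD is only ≈0.6, so it depresses the mean ICC by
≈0.05 — more than twice the (tiny) sampling SD of the nearly-perfect
estimator. The "LOD/2 is safe below 50% censoring" conclusion therefore
holds for moderate-to-large error variances but not in the near-noiseless
corner of the grid; the corresponding acceptance check is left failing on
those three cells rather than softened, and the Richardson–Ciampi fill is
the better choice there.

The `schisterman` strategy replaces below-LOD values by E(W | W > LOD),
conditioning *above* the threshold. That is unusual, but it is implemented
literally as specified for comparison purposes; it predictably biases the
filled values upward.

## RCAL and SIMEX

`rcal()` divides the naive slope by the reliability coefficient
(β* = β̂/ICC) and divides the naive Wald interval endpoints by the same
ICC (Rosner's approach). This is exact arithmetic; the bundled
worked-example tables (`screen_worked_example()`) reproduce a published
screening panel's corrected coefficients from its naive coefficients and
ICCs to printed rounding, and `wald_se_from_p()` rebuilds intervals from
coefficient/p-value pairs.

`simex()` implements the simulation-extrapolation for a single error-prone
predictor: for each λ in {0.5, 1, 1.5, 2}, B contaminated refits with
extra noise of variance λ·σ²𝓌 are averaged, and the mean-slope trend —
including the naive point at λ = 0 — is extrapolated to λ = −1 with a
quadratic. The quadratic extrapolant is the standard practical choice and
a known *under*-correction; on synthetic data RCAL recovers the
generating coefficient essentially unbiasedly while SIMEX recovers most
but not all of the attenuation gap, so RCAL corrections are on average at
least as large. For interval construction the Wald variance is
extrapolated along the same path, with a fallback (rescaling the naive
interval width by |β*/β̂|) when the extrapolated variance is not positive.

`univariate_screen()` ties the pieces together: per-feature naive fit,
RCAL with the feature's own ICC where its error structure is estimable and
the panel median ICC otherwise, SIMEX with the feature's (or median)
within-subject variance, and Benjamini–Hochberg adjustment across the
panel. Degenerate features (constant, separated) are skipped and listed
rather than silently dropped.

## Diagnostics

`roc_auc()` computes the Mann–Whitney AUC (ties counted one half) with a
DeLong interval via the pROC package; the test suite checks it against an
exhaustive concordant-pair enumeration on small inputs. Direction is
always an explicit argument — e.g. the free-to-total PSA ratio *falls* in
prostate cancer — never inferred from the data. `metrics_at_cutoff()`
reports sensitivity and specificity with Clopper–Pearson intervals and
likelihood ratios with Simel log-method intervals (Haldane-corrected when
a 2×2 cell is empty); these interval choices are stated here because
reports of such panels rarely name theirs.

## What the generator does and does not emulate

`generate_repeatability_study()`, `generate_precision_study()` and
`generate_case_control_study()` reproduce the *statistical* structure the
estimators assume: log2-scale variance components, multiplicative error,
LOD censoring, a logistic disease model on true levels, biopsy histology
labels (including occasional AAH subjects that `assign_groups()`
excludes, mirroring the usual cohort arithmetic) and loosely calibrated
PSA/PCA3/creatinine covariates. Defaults mirror the designs the
estimators are meant for: a urinary repeatability study of 20 donors
(16 × 2 + 4 × 3 serial samples, quintuplicate spots, σ²𝓌 = 0.184 and
ICC = 0.48, hence σ²ᵦ = ICC/(1 − ICC)·σ²𝓌), a 5 × 5 precision design
whose variance components correspond to ≈25% intra- and ≈36% inter-assay
CV, and a 70-case / 76-control cohort. A `sigma_spot2` term (default 0)
adds spot-level noise when wanted.

The generator does **not** simulate raw continuous spectra, peak shapes,
adducts, baseline drift, batch effects, or missingness other than LOD
censoring. Passing tests therefore demonstrate that the estimators are
correct *under the declared model*, not that real spectra satisfy that
model.

## Numerical choices and degenerate inputs

* Logistic fits use IRLS (`glm.fit`) with tolerance 1e-8 and at most 50
  iterations; separation is flagged via non-convergence or exploding
  standard errors, and flagged fits are refused by `rcal()` and skipped by
  screens.
* Truncated-normal fills guard against tail-probability underflow by
  returning the threshold itself.
* Quantiles are type-7 (linear interpolation) throughout so reported
  medians/IQRs are reproducible.
* m/z matching is greedy one-to-one by smallest |Δm/z| (ties to the lower
  m/z) within a 0.3 Da window.
* Problem sizes used by the validation suite — 200 replicates of
  n = 2000 cohorts for the attenuation/recovery study (SIMEX B = 50),
  1000 replicates for ICC calibration, a 8 × 3 × 4 × 200 Monte Carlo LOD
  grid, and 200 replicates of a 100-feature, 300-subject screen — were
  chosen as the smallest designs whose Monte Carlo error is comfortably
  below the effect sizes being asserted.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(out_dir = tempfile("pepticc"), seed = 42,
                       n_features = 6, beta_true = c(1.2, -1, 0, 0, 0, 0),
                       simex_B = 25)
res <- run_pipeline(cfg)
head(res$screen)
```

The pipeline writes per-stage CSVs plus a `manifest.json` recording the
seed and package version; rerunning with the same configuration
reproduces the outputs byte for byte.
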