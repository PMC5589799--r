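---
title: "Normative modelling of single-subject brain morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of single-subject brain morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphonorm)
```

This vignette is the package's own account of its statistical machinery: the
model and its assumptions, the tunable parameters and their defaults, what
the synthetic test-bed does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. The feature schema

A scan is a vector over a fixed, ordered catalogue of 2,976 features
(`mn_schema()`), built from

* 15 bilateral volume segmentations (hippocampus, amygdala, thalamus, basal
  ganglia, ventricles, cerebellum, hemispheric tissue compartments, ...),
  each as left / right / asymmetry — 45 features;
* 15 global volumes (midline ventricles, brain stem, corpus-callosum
  subsegments, whole-brain partial volumes) — 15 features;
* 34 Desikan–Killiany plus 74 Destrieux cortical parcellations, each with 9
  surface parameters (GM volume, surface area, mean and SD of thickness,
  mean and Gaussian curvature, curvature and folding index, grey–white
  percent contrast) on left, right and asymmetry — 2,916 features.

The total of 60 volume features is fixed by the catalogue; the exact
composition of the bilateral/global split is a documented convention of this
package, chosen so that typical FreeSurfer-style segmentation output maps
onto it.

## 2. Normalization

**Head size.** All size-dependent measures are rescaled isometrically to a
reference intracranial volume, `x · (eTIV_ref / eTIV)^n`, with the exponent
fixed by dimensional analysis: `n = 1` for volumes, `2/3` for areas, `1/3`
for thicknesses, and accordingly `−1/3` for mean curvature (units 1/length),
`−2/3` for Gaussian curvature, `0` for the dimensionless indices. Two design
choices here: multiplying by the ratio (rather than dividing by `eTIV^n`)
keeps physical units, so normalized values remain readable in reports; and
`eTIV_ref` is the *geometric* mean of the normative cohort's eTIVs, the
natural location parameter under a power law. Under an exact isometric
rescaling of a brain the normalized values are invariant — this is enforced
by a numerical oracle in the test suite.

**Grey–white contrast** depends on the MR sequence, not on head size, so it
is instead rescaled so every scanner-sequence group mean matches the grand
regional mean; the group means learned from the normative cohort are stored
in the model and re-applied to patients. An unseen scanner sequence at
scoring time is an error (the model cannot know that group's contrast
level), with the message advising a re-fit or an explicit mapping to the
closest known group.

**Asymmetry.** Bilateral features yield `AI = (R − L)/(R + L)`, in
`[−1, +1]`, 0 under perfect symmetry, −1 when only the left structure is
present. The denominator convention `(R + L)` (not the half-sum) is adopted
because it makes the stated range exact. AIs are computed from *raw* values:
for volumes the eTIV factor cancels exactly, and keeping one convention for
all parameters preserves the scale-invariance of the index.

## 3. The normative model

`fit_normative()` fits, for every feature in three blocks (raw, normalized,
asymmetry):

* **Age trend.** A polynomial in age of order 0–3 ("low order"), the order
  selected per feature by BIC. BIC rather than a fixed order because the
  majority of features are flat or linear in age and overfitting the trend
  directly inflates false positives at the tails of the age range. Sex and
  scanner-sequence enter as additive covariates by default (`covariates=`),
  reflecting the confounders a normative database retains; covariate
  columns with fewer than two levels are dropped automatically.
* **Artifact screening.** Control residuals are screened by a robust z rule
  (|residual − median| / MAD > 3.5). Screened values are excluded from the
  final coefficient and variance estimates, and the outlier count `k` of
  `n` scans becomes the artifact probability `(k + ½)/(n + 1)` — Haldane
  smoothing keeps the validity odds `(1 − p)/p` finite and positive even
  for clean features. The threshold 3.5 and the rule are configurable
  (`artifact_z`); the defaults follow standard robust-statistics practice.
* **Measurement error.** Repeated scans of the same subject within 3 years
  (`repeat_window`) give within-pair residual differences `d`;
  `measurement_sd = sqrt(mean(d²)/2)`. The root-mean-square form (no mean
  subtraction) is exact for the paired-difference model and behaves
  correctly for a single pair. Pairs that contain a screened-out value are
  dropped from this estimator.
* **Width decomposition.** The stored `population_sd` is the
  measurement-corrected biological spread,
  `sqrt(max(σ_resid² − measurement_sd², 0.01·σ_resid²))`, so that the
  conceptual null width `sqrt(population_sd² + measurement_sd²)` equals the
  residual SD exactly. A naive reading that adds the measurement variance
  to the *raw residual* variance would count measurement noise twice and
  depress the null flag rate by several percent.

### Scoring and calibration

For a new scan the abnormality probability of feature `f` is the two-sided
tail of the *prediction* distribution:

`z = (x − µ̂_f(age, sex, scanner)) / (σ̂_f · sqrt(1 + h))`, `p = 2·P(T_df ≥ |z|)`

with `h` the leverage of the scan's design point and `df` the residual
degrees of freedom. Three refinements matter at the 1% operating point and
are deliberate design decisions:

1. **Student-t, not Gaussian, tails.** With ~300 controls the Gaussian
   approximation under-states the tail by ~5% at `p = 0.01`; the t tail
   with the per-feature df is exact under the model.
2. **Trim de-bias.** Excluding screened outliers trims genuine tail mass
   and biases `σ̂²` low. The correction divides by the expected retained
   variance fraction of a Gaussian trimmed at the screening threshold,
   integrated over the MAD estimator's own sampling noise (which widens
   the effectively trimmed mass); see `.trim_factor`.
3. **Asymmetry-index tails.** An AI residual is, to first order,
   `z₀/(1 + δ)` with `δ` the relative fluctuation of the `(R + L)`
   denominator — a scale mixture with genuinely heavier-than-Gaussian
   tails. At realistic population CVs (6–12%) the plain Gaussian/t tail
   over-flags AI features by 10–17% at the 1% level. The model therefore
   stores each AI feature's denominator CV (robustly estimated from the
   raw block, including its age variation) and computes AI p-values by
   integrating the tail over `δ` with a variance-matching factor. This is
   exact to first order in the CV and restores family-wide null
   calibration; it is the one place where the scoring departs from the
   plain location-scale template, and it is confined to the asymmetry
   block.

The standalone `abnormality_p()` keeps the plain textbook statistic
(Gaussian by default) for didactic use; the model path applies the
refinements above.

**Flags.** `p < alpha` (default 0.01) flags a feature *uncorrected*
(yellow); surviving Benjamini–Hochberg at `q = 0.01` over the family
additionally flags it *FDR* (red). Each variant's family is its 1,989
measured tests plus the 987 asymmetry tests = 2,976 decisions per dataset;
the asymmetry tests are shared between the raw and normalized families, in
line with the quoted family size.

## 4. Fingerprints and regional detections

The signed decadic log, `L = −log10(p)` for positive residuals and
`+log10(p)` for negative ones, maps each feature to a signed significance.
p-values are floored at `1e−16` before the log — extreme deviations occur
in patients, and the floor keeps vectors finite without materially
affecting ordering. Per region and hemisphere the 9 surface parameters
(weight 1) and the 9 asymmetry parameters (weight ½ in each hemisphere's
pool, so the asymmetry's total influence is one region-equivalent) are
condensed with odds-squared weights:

`L_r = sqrt( Σ w·L²·odds² / Σ w·odds² )`.

A measurement flagged as artifact-prone in the normative cohort therefore
loses influence quadratically in its odds. Bilateral volume segmentations
get the same treatment (volume + ½·asymmetry), and global volumes stand
alone — this uniformity is a package decision so that the detection rule
`L_r ≥ 2` means the same thing for every region kind; its side effect is
that single-feature pools fire at the nominal per-feature rate, which
dominates the null detection level. Detections are sorted by `L_r`, ties
broken lexicographically; `top_k(, 3)` implements the stricter specificity
convention. Detection scores are computed on the normalized variant's
p-values (configurable), since head-size-corrected values are the ones
discussed clinically; raw-variant results stay available in the profile.

## 5. Accuracy evaluation

A dataset is *sensitive* for a ground-truth source if any detection is
consistent with it, *specific* if one of the three most prominent
detections is. Granularity is sublobar (region labels), lobar (a fixed
parcellation→lobe table shipped with the package; boundary regions follow a
documented convention), or hemispheric (always used for EEG). Surgery
comparisons require favorable outcome (Engel I–II) and ≥ 6 months
follow-up; anything else is "not applicable", never a 0. Aggregates are
fractions of consistent among evaluable datasets.

Regional 2×2 tables yield `DOR = LR⁺/LR⁻ = (tp·tn)/(fp·fn)` with a +½
continuity correction on all cells when any cell is empty (keeping
`log(DOR)` finite), plus PPV/NPV. Group differences use randomization tests
(default 10,000 resamplings, two-sided via |statistic|, `+1` convention so
p is never 0) for categorical data, and sequential Kruskal–Wallis →
pairwise Mann–Whitney for ordinal data, with α = 0.01 significant and
p < 0.05 marginal ("trend"). Fisher's exact test and the exact binomial
tail `P(X ≥ k | n, p₀)` cover the remaining comparisons.

## 6. Subtype-representative features

For one subtype's fingerprint matrix, `t_f = mean_f / sd_f` measures how
reproducibly feature `f` deviates; features outside the Tukey fences
(Q1 − 1.5·IQR, Q3 + 1.5·IQR) of the pooled `t` distribution over all 2,976
features are *reproducible*. Features whose mean differs from **every**
other subtype (pairwise Welch t-tests, all p < 0.01; pooled and
Mann–Whitney variants available) are *unique*. The selection is the
intersection; importances are mean |L| over the subtype, normalized to sum
to one. Open points resolved here: unbiased SD in `t_f`; fences computed
globally per subtype matrix (the notion of "extraordinarily large" is
relative to the feature population); `sd_f = 0` features get a capped
signed surrogate and are reported as degenerate.

## 7. The synthetic test-bed

`sim_config()` freezes a "world": per-(region, parameter) baselines at
physiologically plausible values (hippocampus ≈ 4.1 ml, cortical thickness
2–3.2 mm, ...), polynomial age trends (orders 0–2, mostly mild decline),
region-specific population CVs of 6–12%, measurement error at 30–50% of the
biological SD, additive scanner offsets (0.25 biological SDs), multiplicative
contrast factors per sequence, and left/right subject-effect correlation
0.6. The world seed is fixed independently of cohort seeds, so all cohorts
live in the same world. Default cohort sizes — 300 control scans of 260
subjects with 40 repeat pairs, ages 7–79, three scanners — mirror a
single-centre normative database at desk cost; the same sizes are used by
the acceptance checks.

`generate_controls()` adds 1% gross value-level artifacts (multiplicative
factors 0.2–0.55 or 1.8–3), emulating unreviewed segmentation failures.
`generate_patients()` is artifact-free by default: it emulates patient
datasets that *passed* quality control, which is the population every
downstream comparison uses. Subtype templates inject, e.g. for left
MTLE-HS, −4 SD left hippocampal volume, −1.5 SD amygdala, −2 SD ipsilateral
temporal thickness; ground truth records the injected regions, an EEG
lateralization matching the injected side (configurable discordance), and a
favorable-outcome mesiotemporal resection for a configurable fraction.

What the generator deliberately does **not** emulate: spatial correlation
between neighbouring parcellations, non-Gaussian biology (skewed ventricle
volumes), site effects beyond additive/multiplicative offsets,
disease-secondary widespread effects, or realistic artifact structure
(artifacts hit single values independently). Passing tests therefore
demonstrate statistical correctness of the machinery under its stated
model, not clinical performance on real MRI.

## 8. Numerical choices and degenerate inputs

* Trend design uses centred/scaled age for conditioning; coefficients are
  rebased to natural age only for display.
* Exact fits (RSS ≈ 0) are floored so BIC resolves ties toward the lowest
  order; constant features come out as order 0 with SD ≈ 0.
* Residuals numerically at zero report sign 0 (tolerance 1e−12 in z).
* p-values are clipped to (0, 1]; logs are floored at p = 1e−16.
* Zero-variance fingerprint vectors give NA correlations with a warning;
  `sd = 0` features in selection get a capped surrogate.
* Leverage for outlier-refitted features reuses the shared full-design
  Gram matrix — the difference is O(1/n²) and immaterial at n ≈ 300.
* Randomization p-values use the `(1 + count)/(N + 1)` convention.

## 9. Problem sizes used in the checks

The packaged acceptance checks run at the default study conditions: a
300-scan normative fit, 200 held-out null subjects for calibration
(595,200 binomial decisions per family), 100 simulated patients per
recovery experiment, and four 9-scan subtype cohorts (including repeats)
for the reproducibility analysis. These sizes were chosen to keep every
Monte-Carlo estimate's sampling error well below the tolerance it is
compared against, at a few minutes of desk compute.

## 10. Known limitations

* The Gaussian location-scale model is assumed per feature; genuinely
  skewed features (ventricles in aging cohorts) would need transformation
  before fitting.
* The artifact model is value-wise and independent; correlated artifact
  patterns (a failed hemisphere surface) are not represented, and validity
  odds are feature-level, not scan-level.
* Scanner harmonization is additive/mean-matching only; no interaction
  with age is modelled.
* Extrapolation beyond the normative age range is allowed but only
  annotated, not penalized.
* The lobe lookup is a fixed convention; boundary parcellations
  (paracentral, parieto-occipital sulcus) could defensibly be assigned
  otherwise, which would shift lobar-level (not sublobar) agreement.
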