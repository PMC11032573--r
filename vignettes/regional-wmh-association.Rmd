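---
title: "Regional WMH volumetry and determinant mapping: methods"
author: "wmhregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional WMH volumetry and determinant mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhregions)
```

## The scientific problem

White matter hyperintensities (WMH) on FLAIR/T2 MRI are a hallmark of
cerebral small vessel disease, but they are aetiologically heterogeneous:
arteriolosclerosis (driven by cardiovascular risk) and cerebral amyloid
pathology both increase WMH burden, and there is long-standing evidence
that they do so in *different places* — vascular risk preferentially in
anterior/superior white matter, amyloid in posterior regions. Testing that
anterior–posterior dissociation requires (i) regional rather than global
WMH volumetry, (ii) harmonized determinants across heterogeneous cohorts,
and (iii) models that absorb between-site differences. This package
implements that analysis chain, plus a simulator that generates multi-site
cohorts with *known* regional effect structure so every stage can be
validated without access to patient data.

## Regional volumetry

Inputs are per-subject binary WMH masks already registered to a common
template grid (1 mm isotropic MNI-152 in the motivating application;
registration itself is out of scope and grid mismatches are treated as hard
errors — no silent resampling). Processing is:

1. **White-matter masking** (`apply_wm_mask`): lesion voxels where the WM
   probability map is below threshold (default 30%) are removed, limiting
   contamination by misclassified non-WMH lesions. The comparison is
   *inclusive* (`>= 0.30`): a voxel exactly at the threshold is retained,
   the common convention for probabilistic tissue maps. The operation is
   idempotent and monotone in the threshold.
2. **Bilateral merging** (`merge_bilateral`): left/right labels sharing a
   stem name collapse into one ROI; midline labels stand alone. On a
   50-label tract atlas (22 pairs + 6 midline) this yields the 28 analysis
   ROIs.
3. **Volumetry** (`regional_volumes`): volume is voxel count times voxel
   volume, reported in millilitres. The *total* WMH volume counts all
   masked lesion voxels, including those inside white matter but outside
   every atlas ROI — so the ROI volumes sum to at most the total, and the
   total-adjustment covariate is not merely the ROI sum.
4. **Cube-root transform** (`cube_root_transform`): WMH volumes are
   strongly right-skewed; \(v \mapsto v^{1/3}\) is the standard
   variance-stabilising transform applied before regression.

## Determinants

**Vascular risk compound score (VRCS).** Six predefined indicators
(current smoking, hypertension, hypercholesterolemia, diabetes mellitus,
obesity with BMI ≥ 30, history of a vascular event other than stroke) are
coded present/absent/missing. The score is the proportion of present
factors among the available ones, with equal weights, and is only defined
when at least three indicators are available; otherwise the subject is
excluded from VRCS models. For analysis the score is z-transformed over
the pooled analysis sample (`standardize_vrcs`), not per site, so one unit
is one pooled SD of vascular risk burden.

**Amyloid-β42 status.** Cohorts measure amyloid with different assays, so
positivity is harmonized through a rule registry (`amyloid_rules`): CSF
rules call a value *strictly below* the local cutoff positive (the shipped
defaults are 640 ng/L for the sandwich-ELISA assay, 694 pg/mL for the
INNOTEST mixture-model cutpoint, 1096 pg/mL for the CRM-anchored
mass-spectrometry assay), and PET rules call an SUVR *at or above* the
cutoff (default 1.5) positive. Boundary handling follows the cutoff
definitions literally: a CSF value exactly at the cutoff is negative, a
PET SUVR exactly at the cutoff is positive. Status is coded positive = 1;
sex is coded female = 1. These codings fix the sign convention of every
reported coefficient.

## The per-ROI model

For each determinant \(d\) (VRCS z-score, or amyloid status) and each
merged ROI \(r\), a separate linear mixed model is fitted:

\[ y_{sr} = \beta_0 + B\, d_s + \beta_a\,\mathrm{age}_s +
   \beta_x\,\mathrm{sex}_s \,[+\, \beta_t\, t_s] + u_{site(s)} +
   \varepsilon_{sr}, \qquad u \sim N(0, \tau^2),\;
   \varepsilon \sim N(0, \sigma^2) \]

where \(y_{sr}\) is the cube-root regional volume, z-scored by default over
the model's own analysis sample, and \(t_s\) is the cube-root, z-scored
total WMH volume included in the adjusted runs. Every model is fitted both
without and with total-WMH adjustment: adjustment separates regional
specificity from effects mediated by overall lesion burden.

Numerical choices:

* Variance components by REML (`lme4::lmer`); Wald z p-values on the
  determinant coefficient. With large multicenter samples the normal
  reference is standard and reproducible across implementations.
* \(\tau^2\) is floored at zero: with a single site, or when the REML fit
  is singular (\(\hat\tau^2 = 0\)), the GLS solution coincides with OLS
  and the model is refitted by `lm`, recorded in the result's `method`
  column. A property test holds the two paths together to 1e-8.
* `fit_roi_model(varcomp = c(tau2, sigma2))` computes the closed-form GLS
  fixed effects at *fixed* variance components; this is the hook used to
  verify the estimator against an independent dense-matrix oracle.
* Complete cases are taken per model: a subject missing the determinant at
  hand (or age/sex/site) is dropped from that model only. z-scores are
  computed over exactly that per-model sample, keeping coefficients
  interpretable as SD units of the analysed subjects.
* A ROI whose outcome has zero variance in the analysis sample is skipped
  with a warning and reported as an NA row, so the result table always has
  one row per determinant × ROI × adjustment.
* Multiplicity: Bonferroni over the ROI family, `alpha_family / n_tests`
  with strict `<`; `n_tests` stays fixed at the number of merged ROIs (28
  for the full atlas, i.e. a threshold of 0.0018, commonly quoted as
  p < 0.002) even when ROIs are skipped.

Two sensitivity analyses rerun the identical pipeline on subsets: exclusion
of a named cohort (for independent replication of a cohort-specific
finding) and restriction to subjects with *both* determinants defined (so
differences between the two main analyses cannot be due to sample
composition). Both keep the determinant → regional-volume direction of the
main analysis.

## The synthetic cohort and lesion generator

`sim_config` + `simulate_subjects` + `simulate_lesions` generate a
multi-site memory-clinic cohort with known ground truth:

* **Demographics**: age ~ Normal(71.5, 9) truncated to [40, 100]; 50%
  female; balanced site assignment. Defaults mirror the published
  multicenter memory-clinic profile the package targets.
* **Risk indicators**: Bernoulli with prevalences (0.216, 0.513, 0.490,
  0.204, 0.112, 0.289) for smoking, hypertension, hypercholesterolemia,
  diabetes, obesity, vascular-event history, then masked to missing at
  per-indicator rates (0.26, 0.03, 0.29, 0.24, 0.78, 0.21). The *true*
  (unmasked) indicators define the latent VRCS that drives lesion load, so
  observed-score measurement error is part of what downstream recovery
  tests experience.
* **Amyloid**: true status Bernoulli(0.59), emitted as a continuous
  CSF-like value at cutoff ∓ |N(30, 10)| for positive/negative subjects,
  so the dichotomization stage is genuinely exercised. Measurements are
  available for everyone by default; cohort-style unavailability can be
  switched on (`amyloid_missing_rate`). VRCS and amyloid status are
  generated independently, matching the reported absence of correlation
  between them.
* **Lesions**: for each merged ROI the cube-root volume follows the linear
  model of the analysis stage (baseline + age + sex + ROI-specific
  determinant effects + a shared lesion-load factor + site offset + noise),
  clamped at zero before cubing (volumes are nonnegative). The implied
  voxel count is placed inside the ROI's block, nearest-to-a-random-seed
  voxel first with random tie-breaks; connectivity is not guaranteed, which
  is irrelevant for count-based volumetry. Counts above the ROI capacity
  are capped with an aggregated warning. One global seed fans out into
  per-stage and per-subject substreams, so outputs are bit-identical for
  identical configs regardless of call order.
* **Shared lesion-load factor**: the `gamma_vrcs`/`gamma_abeta` terms load
  every ROI (weighted by `loading`), mimicking determinants whose regional
  association is mediated by total lesion burden. This is the mechanism
  that makes total-WMH adjustment attenuate coefficients, as a real
  confounded association would.

The generator emulates covariate structure, site heterogeneity and
count-exact regional lesion load. It does **not** emulate realistic lesion
morphology, periventricular/deep gradients, registration error, or
segmentation noise — so passing tests validate the statistical chain, not
robustness to imaging artefacts.

**Effect sizes in SD units.** `baseline_outcome_sd()` returns the
cube-root-scale outcome SD implied by the nuisance terms
(\(\sqrt{\sigma^2 + \tau^2 + (\beta_{age}\,sd_{age})^2 + (\beta_{sex}/2)^2}\),
about 0.245 under defaults). Simulation studies express determinant
effects as multiples of this quantity, e.g. a "0.3 SD" effect is
`0.3 * baseline_outcome_sd(cfg)` on the raw scale, which is ~0.3 on the
z-scored analysis scale.

## What the validation suite establishes

Problem sizes were chosen so the full suite runs comfortably on a single
CPU: oracle equivalences on 16³ fixtures; a 500-replicate null simulation
(n = 500, 28 ROIs, no site heterogeneity) for the family-wise error; a
200-replicate null on the compact 6-ROI layout for p-value uniformity; and
one n = 1000 end-to-end signature-recovery experiment on the 28-ROI
layout.

One honest caveat on the signature experiment: with n = 1000, a binary
determinant at 59% positivity, and the Bonferroni threshold over 28 ROIs
(Wald z > 3.12), a 0.3-SD effect yields a per-ROI Wald z around 4.7 and
per-ROI power near 0.94 — high, but not so high that recovering *all*
affected ROIs with *zero* null exceedances is guaranteed in any single
realisation. The per-test error rate itself is correctly calibrated (the
null simulations verify this); the exact-support event is simply a
conjunction of ~56 marginal events. Readers reproducing the experiment at
other seeds should expect occasional single-ROI deviations from the exact
pattern, with the family-wise error bound still holding.

## Known limitations

* No voxel-wise inference, interaction or mediation models; the package
  maps marginal determinant–ROI associations only.
* Harmonization of the risk indicators themselves (from raw clinical data
  to present/absent) is upstream of this package.
* The mixed model assumes a common residual variance across sites; gross
  violations would call for per-site weights that are not implemented.
* Masks, atlas and WM map must share one grid; bring your own registration.
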