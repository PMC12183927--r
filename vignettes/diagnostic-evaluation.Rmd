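---
title: "Evaluating blood biomarkers against a CSF amyloid reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating blood biomarkers against a CSF amyloid reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbadx)
```

# The evaluation problem

A memory-clinic patient with cognitive decline can have amyloid pathology
confirmed by lumbar puncture: a CSF Aβ42/40 ratio at or below 0.069 is
abnormal (A+), strictly above is normal (A−). Plasma biomarkers — Aβ42,
Aβ40, their ratio, pTau181, pTau217, and NfL, all in pg/ml — promise the
same answer from a blood draw. `bbadx` quantifies how well each plasma
marker recovers the CSF-defined label, and how stable that performance is
under realistic measurement error.

Two conventions run through everything:

* **Boundary rule.** Assay reference ranges define *normal* by strict
  inequality (e.g. Aβ42/40 > 0.069, pTau181 < 56.5 pg/ml), so a value
  exactly at a cut-off is classified abnormal. The ROC layer mirrors this:
  after orientation, the positivity predicate is `score ≥ threshold`.
* **Orientation.** Markers depressed in A+ (Aβ42 and the ratios) are
  negated internally so the AUC is always ≥ 0.5; cut-offs are reported on
  the original scale with the direction recorded.

# The synthetic cohort generator

No subject-level data ship with the package; the generator produces cohorts
with the *published statistical structure* of a 102-subject memory-clinic
sample: 33 A− and 69 A+ subjects; group-specific age (66.9 ± 8.6 vs
73.0 ± 6.1 years), ApoE ε4 carriage (18% vs 49%), MCI/dementia mix, and a
10/102 missing-diagnosis rate; and group-conditional means and SDs for all
nine biomarker concentrations.

Design choices, fixed once and not tuned afterwards:

* **Lognormal marginals, moment-matched.** Concentrations are positive and
  right-skewed (the Shapiro–Wilk routing in the contrast layer almost always
  selects the Wilcoxon test on such data). Given a target mean m and sd s,
  σ² = ln(1 + s²/m²) and μ = ln m − σ²/2 reproduce the moments exactly;
  `lognormal_from_moments()` is tested by closed-form round-trip.
* **Latent Gaussian copula.** A single correlation matrix on the latent
  scale couples the markers: 0.7 within an analyte family (amyloid: CSF
  Aβ42, plasma Aβ42/Aβ40; tau: tTau, CSF pTau181, plasma pTau181/pTau217),
  0.3 across families. True cross-marker correlations are not published;
  these defaults produce the strong plasma-pTau/CSF-pTau association seen in
  such cohorts and are declared in the shipped
  `inst/extdata/table12_default.yaml`, not claimed to be estimates.
* **Label consistency by construction.** The CSF Aβ42/40 ratio *is* the
  reference standard, so the generator must not create label noise. The
  ratio is drawn per group from a truncated normal (A−: N(0.09, 0.01) above
  0.069; A+: N(0.05, 0.01) below; rejection sampling capped at 10,000
  attempts per subject), and CSF Aβ40 is derived as `csf_ab42 / ratio`.
  Consequence: eight concentrations are moment-matched primaries, while CSF
  Aβ40's moments are emergent (within ~5–8% of the configured location).
  Moment-recovery tests therefore cover the primaries; the ratio's mild
  truncation bias (the clipped tail mass is < 3% per group) is accepted as
  the price of an exactly clean label.
* **Heavy plasma-ratio tails.** Plasma Aβ42 and Aβ40 carry a 5% outlier
  rate at scale 3 (multiplied or divided with equal probability), emulating
  the outlier-driven degradation of the plasma ratio seen in practice.
  Moment-fidelity checks disable the contamination, since its purpose is to
  distort moments.
* **Seeding.** One master seed fans out to per-stage substreams
  (demographics, copula, reference ratio, outliers, MMSE), so changing the
  MMSE stage, say, cannot perturb the biomarker draws. For
  coefficient-recovery studies the MMSE stage can be switched to an injected
  linear model (`mmse_model`), in which case the score is left unclipped so
  coverage checks are unbiased; default-mode MMSE is clipped to [0, 30].

What the generator does **not** emulate: assay-specific pre-analytical
biases (renal function, BMI, centrifugation delays), longitudinal drift,
and the true (unpublished) shapes and correlations of the source
population. Passing tests on synthetic cohorts therefore demonstrate that
the *machinery* is correct and that the qualitative contrasts survive
realistic structure — not that any specific clinical cohort would give the
same numbers.

# Statistical machinery

**Group contrasts.** Each group is tested for normality by Shapiro–Wilk at
α = 0.05; both groups normal routes to a Welch t-test (group SDs in this
setting differ up to threefold, making the equal-variance t imprudent),
otherwise Wilcoxon rank-sum. Cohen's d uses the pooled SD with the n−2
denominator and a normal-approximation CI (d ± 1.96 se); the percent median
difference is computed from data medians, never from means. ANCOVA
adjustment is the Wald p on the group indicator in
`biomarker ~ group + age + sex`.

**ROC and DeLong.** The AUC is the Mann–Whitney pair statistic with
half-credit ties, computed by midranks; its numerator is an exact
half-integer, so the implementation agrees bit-for-bit with exhaustive pair
counting (a property enforced over 1,000 random instances in the tests).
Variance and paired covariance use DeLong structural components in the
midrank formulation; the suite cross-checks both against `pROC` to 1e-10
and against a 2,000-resample bootstrap (within 25%). CIs are Wald on the
AUC scale, clipped to [0, 1], matching the symmetric intervals such studies
print. Youden cut-offs break ties toward specificity, reflecting the
rule-in framing of confirmatory blood testing; the two-cut-off layer
reports the least extreme thresholds reaching 95% specificity (rule-in) and
95% sensitivity (rule-out), with the intermediate-zone fraction. An
unattainable target is a flagged missing cut-off, not an error, because
degenerate score distributions are a legitimate input. PPV/NPV default to
the analyzed sample's prevalence (69/102 for the full default cohort) and
are overridable, since predictive values are prevalence-dependent by
construction.

**Models.** Logistic fits standardize the *predictor only* (z-score on the
analysis sample): log-odds per predictor SD is what makes coefficients
comparable across markers whose units differ by three orders of magnitude.
Outlier exclusion is one pass at mean ± 3 SD on the full sample — no
iteration, so the rule cannot cascade. Complete separation is flagged, not
fatal. The MMSE models are ordinary least squares with dementia as the
diagnosis reference level (so the MCI indicator is positive) and subjects
with missing diagnosis excluded from these models only.

**Robustness.** Noise is multiplicative Gaussian, x(1+e) with e ~ N(0, cv):
a CV is a relative-error concept and concentrations are positive. The grid
is 0 to 0.25 in steps of 0.025 with 500 replicates per point; orientation is
frozen from the unperturbed data so extreme noise cannot flip a marker's
direction mid-simulation. Ratios are perturbed in numerator and denominator
independently, which amplifies the effective ratio CV by √2 — the mechanism
behind the plasma Aβ42/40 ratio's fragility relative to the pTau markers.
Values are clipped below at 1% of the original; at cv ≤ 0.25 the clip is a
< 1e-4 tail event, but at extreme noise (cv ≈ 3) the floor preserves
residual rank information, so the mean AUC approaches 0.5 without reaching
it exactly — the tests check this regime against an independent
pair-probability oracle rather than asserting exact 0.5.

# Problem sizes

The package's simulations are sized so each analysis is stable without
being wasteful: moment-fidelity checks run at 5,000 subjects per group
(Monte-Carlo SEs small enough for 3-SE bands to bite), robustness contrasts
on a tenfold-scaled cohort (330/690) with 500 replicates per grid point,
coefficient-recovery at 200 study-sized (n = 102) cohorts, and DeLong
calibration on twenty n = 100 cohorts with 2,000 bootstrap resamples.

# Known limitations

* Printed summary moments under-determine a joint distribution; every
  distributional choice above is an assumption, declared in the config, and
  conclusions drawn from synthetic cohorts are about the machinery and
  qualitative orderings, not point reproduction of any study's tables.
* The normal-approximation CI for Cohen's d is slightly narrow at n ≈ 30
  per group compared with noncentral-t intervals.
* DeLong inference assumes independent subjects; clustered or repeated
  measurements would need a different variance estimator.
* The two-cut-off thresholds sit on observed order statistics, so at
  n ≈ 100 their sampling variability is substantial; they should be read as
  distributions (the test suite checks them distributionally), not as
  transferable constants.
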