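---
title: "Compactness-based bAVM morphology and post-SRS hemorrhage analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compactness-based bAVM morphology and post-SRS hemorrhage analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmcompact)
```

## The problem

A brain arteriovenous malformation (bAVM) is a tangle of abnormal vessels —
the *nidus* — shunting arterial blood directly into veins, with an annual
rupture risk of roughly 1–4%. Stereotactic radiosurgery (SRS) treats the
nidus with a single focused radiation session; obliteration takes years,
during which hemorrhage risk persists. Nidi differ in texture: *compact*
nidi are dense vascular balls, while *diffuse* nidi intersperse vessels with
functioning brain. This package implements an observer-independent
morphology measure — the compactness index — computed by automated tissue
segmentation of the irradiated volume, together with the survival analytics
needed to relate morphology to post-SRS hemorrhage: person-year incidence,
Kaplan–Meier/log-rank comparisons against a simulated untreated natural
course, and Cox proportional-hazards modelling with backward selection.

## Segmentation model

The analysis volume is the **prescription isodose volume**: every voxel
receiving at least the prescribed margin dose. Two numerical steps precede
clustering:

* **Dose resampling** (`resample_dose()`): the planning dose grid rarely
  matches the T2-weighted MRI grid, so the dose is trilinearly interpolated
  in world (mm) coordinates onto the T2 grid. Points outside the dose grid
  receive 0 Gy; fully disjoint grids are an error. Trilinear interpolation
  is exact for affine fields and is the standard choice for smooth dose
  maps.
* **ROI extraction** (`prescription_roi()`): the mask `dose >= margin_dose`.
  The boundary is included — the prescription isodose volume by definition
  contains the surface at exactly the margin dose — and a `strict` flag is
  available because the alternative reading ("exceeding" as `>`) differs
  only on a measure-zero surface in continuous dose fields.

Within the ROI, voxel intensities are clustered by **fuzzy c-means** into
`c = 3` classes. For scalar intensities `x_i` and centroids `c_k`, FCM
alternates

* memberships `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` with
  `d_ik = |x_i - c_k|` (a point coinciding with a centroid gets a crisp
  membership of 1 there), and
* centroids `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`,

until the largest centroid movement falls below `tol` (default `1e-5` of the
intensity range) or `max_iter = 300` iterations. The objective
`J = sum u^m d^2` is non-increasing across iterations, which the tests
assert on every run. Because the data are one-dimensional, FCM is
equivariant under affine intensity rescaling (provided the tolerance is
expressed relative to the range, as here), so no intensity normalisation is
applied — a deliberate choice, also verified by a test.

**Initialisation.** The first restart places centroids at the 10th/50th/90th
intensity percentiles — deterministic and, for three roughly balanced
classes, close to the basin of the global optimum. Four further restarts
draw centroids uniformly within the intensity range under the configured
seed; the restart with the lowest final objective wins. Non-convergence is
flagged, not an error.

**Tissue assignment.** On T2-weighted MRI, fast-flowing blood appears as a
signal void (darkest), brain parenchyma intermediate, CSF brightest. The
sorted centroids therefore map to vessel < brain < CSF, independent of
input order; two centroids agreeing within tolerance make the ordering
unresolvable and raise an error rather than silently guessing.

**Proportions and compactness.** Each ROI voxel is hard-assigned to its
maximum-membership class (ties, which occur only on measure-zero boundaries,
go to the lower class index and this rule is fixed, not random). The
**compactness index** is

CI = vascular proportion (%) / brain-tissue proportion (%),

and a nidus is **compact** when CI ≥ 0.63. The 0.63 operating point is
shipped as a constant default: it was derived on a patient registry that is
not distributable, so the package recovers *that kind* of cutoff from
synthetic data (see below) but does not re-derive the number itself. The
boundary is inclusive, following the operational definition "compact is
CI ≥ 0.63"; a `boundary_compact` switch exposes the strict reading.

## Cutoff selection

`roc_curve()` enumerates every achievable operating point exactly:
thresholds are the midpoints between consecutive distinct scores plus
sentinels at ±∞, and sensitivity/specificity are obtained by counting —
no smoothing, no parametric assumption. `youden_cutoff()` maximises
J = sensitivity + specificity − 1, breaking ties toward the smallest
threshold (flagged via a message). On simulated cohorts where the outcome
depends on CI ≥ 0.63 with 10% label noise, the recovered cutoff lands
within ±0.05 of 0.63 at n = 2000 — the property the acceptance suite
checks in place of the unavailable registry derivation.

## Survival analytics

* **Person-year rates** (`person_year_rate()`, `rate_table()`): events
  divided by summed years at risk, reported per 1000 person-years. Reported
  values are rounded half-up to one decimal *at report time only*; internal
  values stay unrounded. Volume strata default to < 20, 20–40 (inclusive at
  both ends) and > 40 cm³. A patient with two bleeds contributes two
  at-risk observations — the published convention — which the demonstration
  cohort reproduces; this slightly understates variance and is documented
  rather than corrected.
* **Kaplan–Meier and log-rank** (`km_estimate()`, `logrank_test()`): the
  product-limit estimator and the K-sample observed-minus-expected
  statistic with hypergeometric variance, via the `survival` package, with
  events handled before censorings at ties. Independent oracles in the test
  suite (hand-tabulated O−E/V, closed-form exponential survival) guard the
  wrapper.
* **Natural course** (`simulate_natural_course()`): the untreated
  comparator assumes a constant annual bleeding probability p = 0.022.
  Event times are exponential with λ = −ln(1 − p) — the unique constant
  hazard making "2.2% per year" exact — censored at each subject's observed
  follow-up, and the closed form S(t) = (1 − p)^t is returned for overlay.
  The comparison with an observed cohort is a log-rank test against a
  simulated cohort sharing the observed follow-up times; the simulation
  mechanics are a package design choice, seeded and reproducible.
* **Cox model** (`cox_fit()`, `backward_select()`): Breslow partial
  likelihood by default (ties are rare in continuous follow-up; Efron is a
  flag), Wald 95% CIs `exp(beta ± 1.96 se)`. Backward selection repeatedly
  drops the term with the largest Wald p above α = 0.157 — a lenient
  criterion approximating AIC-based selection — while enforcing hierarchy:
  a main effect is never removed while an interaction containing it stays.
  The elimination path is returned for audit. Rank-deficient designs error
  with the collinear columns named; near-monotone likelihoods produce a
  warning naming the covariate.

## What the synthetic data emulate — and what they do not

`generate_phantom()` builds a spherical (or ellipsoidal) nidus in which a
Gaussian-smoothed white-noise field, thresholded at the empirical quantiles
of the target composition, carves spatially coherent tissue classes; the
realised proportions match the targets to within one voxel by construction.
The smoothing FWHM (default 3 voxels) controls texture scale: large FWHM
gives the coarse clumps of a compact nidus, small FWHM fine diffuse
intermixing. This is a *proxy* for real nidus texture, not a claim about
it — the morphology literature defines compactness through the index, not
through a generative texture model. Intensities are class-conditional
normals (means 60/140/220, SD 20 on an arbitrary 8-bit-like scale — a
4-SD class separation typical of good T2 contrast); the dose falls off
quadratically from the centre and equals the margin dose exactly on the
nidus boundary, so the ROI and the nidus coincide and ROI-extraction
accuracy is testable against ground truth.

Consequently, passing tests demonstrate correct *algorithmic* behaviour —
quantile-exact composition recovery, FCM tracking the nearest-true-mean
(Bayes) assignment within 2 percentage points, CI recovered within ±0.05 —
under idealised imaging. They do not demonstrate robustness to bias fields,
partial-volume averaging beyond class mixing, registration error, or
motion; none of these are modelled.

`generate_cohort()` draws per-stratum exponential event times from annual
probabilities (λ = −ln(1 − p)), censors at follow-up times drawn from a
configurable distribution, and fills covariates from distributions spanning
the published cohort ranges. Real registries have informative censoring,
correlated covariates and time-varying hazards; none are modelled, which is
exactly why fitted hazard ratios from the publication are out of scope
while *operating characteristics* (type-I error of the log-rank test,
coverage of the planted hazard ratio, selection behaviour at α = 0.157)
are in scope.

The demonstration cohorts written by `make_demo_data()` reproduce the
published stratified (events, person-years) tallies *by construction*:
each stratum cell gets its printed event count and total follow-up.
Because the two published stratifications (morphology × volume group and
Spetzler-Martin group × morphology) disagree at their shared margins by a
few person-years, no single cohort can satisfy both exactly, and two CSVs
are written. Within-cell follow-up is uniform across observations — rate
arithmetic depends only on cell sums, but the Kaplan–Meier shapes of these
demonstration cohorts are therefore not meaningful.

## Numerical choices and degenerate inputs

* Proportion targets must sum to 100 (the default composition rescales the
  published marginal medians 30.9/52.2/16.8, which sum to 99.9, preserving
  their ratios).
* FCM requires at least as many distinct values as clusters; fewer is a
  degenerate-input error. Zero distances give crisp memberships.
* An empty prescription ROI (margin dose above the whole field) is an
  error naming the stage; `segment_bavm()` prefixes every stage failure
  with the stage name.
* Grids carry spacing and origin; phantom NIfTI output uses double
  precision so round-trips are voxelwise exact.
* Seeds: every stochastic routine takes an explicit integer seed;
  `run_pipeline()` stamps seeds and a configuration hash into its report,
  and reruns are byte-identical.

## Problem sizes

The test and acceptance workloads were sized to be decisive yet quick on a
laptop: 96³ phantoms (≈ 33,500 in-nidus voxels) for study-scale
segmentation recovery and 48³/64³ for unit tests; 30,000-point mixtures for
the FCM/Bayes comparison; n = 2000 for cutoff recovery; 50,000 subjects for
the natural-course closed-form check; 2000 replicates for log-rank type-I
error; and 100 replicates (n = 400, ~40% events) for backward-selection
operating characteristics.

## Known limitations

* Intensity-only clustering cannot beat the Bayes error of overlapping
  class distributions; with heavy overlap (< 3 SD separation) proportion
  recovery degrades and the package makes no promise there.
* The 0.63 cutoff and the published multivariable hazard ratios are
  registry-derived facts, reported as defaults/constants, not reproduced.
* Duplicating a two-bleed patient treats the bleeds as independent; a
  recurrent-event model (Andersen–Gill, frailty) would be more efficient
  and is out of scope.
* The natural-course comparison inherits the strong assumption of a
  constant 2.2%/yr hazard irrespective of anatomy.
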