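# avmcompact

Quantitative morphology and hemorrhage-risk analytics for brain
arteriovenous malformations (bAVMs) treated with stereotactic radiosurgery
(SRS).

Whether a bAVM nidus is *compact* (a dense vascular tangle) or *diffuse*
(vessels interspersed with intervening brain) matters for radiosurgical
outcome, but the distinction is usually an eyeball call. `avmcompact`
implements a fully automated, reproducible alternative and the survival
analyses that go with it, aimed at neurosurgeons, radiation oncologists and
imaging scientists who study SRS outcomes:

1. **Automated nidus segmentation.** The planning dose map is trilinearly
   interpolated onto the T2-weighted MRI; the region of interest is the
   *prescription isodose volume* — every voxel receiving at least the
   prescribed margin dose. Within it, voxel intensities are clustered by
   fuzzy c-means (FCM) into three tissues, using the T2 brightness ordering
   flow-void vessel < brain parenchyma < CSF. FCM minimises

   J(U, c) = Σᵢ Σₖ uᵢₖᵐ ‖xᵢ − cₖ‖², with uᵢₖ = 1 / Σⱼ (dᵢₖ/dⱼₖ)^(2/(m−1)),

   where m > 1 is the fuzzifier (default 2).

2. **Compactness index (CI).** CI = vascular proportion (%) / brain-tissue
   proportion (%) inside the ROI. A nidus is *compact* when CI ≥ 0.63 and
   *diffuse* otherwise; the cutoff is chosen by maximising the Youden index
   J = sensitivity + specificity − 1 along the empirical ROC curve.

3. **Survival analytics.** Person-year incidence rates (events per 1000
   person-years) with stratified rate tables, Kaplan–Meier curves and
   K-sample log-rank tests, a simulated untreated natural course with a
   fixed annual bleeding probability p (hazard λ = −ln(1 − p), so
   S(t) = (1 − p)ᵗ; default p = 0.022), and Cox proportional-hazards models
   with interaction terms and backward stepwise selection (Wald-p stopping
   criterion 0.157).

4. **Synthetic data.** Imaging phantoms with known tissue composition and a
   dose field whose margin-dose isosurface coincides with the nidus
   boundary, plus simulated cohorts with exponential per-stratum hazards —
   so every stage of the pipeline is testable without patient data.

## Worked example

Segment a synthetic nidus built at the published median tissue composition
(30.9 / 52.2 / 16.8 % vessel / brain / CSF) and classify its morphology:

```r
library(avmcompact)

spec    <- phantom_spec(grid_shape = c(64, 64, 64), nidus_radius = 16, seed = 1)
phantom <- generate_phantom(spec)
seg     <- segment_bavm(phantom$t2, phantom$dose, spec$margin_dose,
                        fcm_params(seed = 1), phantom$grid, phantom$grid)
seg
#> bAVM segmentation: 17256 ROI voxels (converged)
#>   proportions: vessel 31.2%, brain 51.1%, csf 17.7%
#>   centroids: 58.5 / 139.3 / 218.4
#>   compactness index: 0.609

classify_morphology(seg$compactness_index)
#> [1] "diffuse"
```

The 17,256 ROI voxels are the prescription isodose volume (here exactly the
nidus). The recovered proportions sit within 1.2 percentage points of the
ground truth, and the compactness index 0.609 — just below the 0.63 cutoff —
calls the nidus diffuse.

Person-year rate arithmetic and a stratified rate table from the bundled
demonstration cohort (whose stratum totals equal the published tallies by
construction):

```r
person_year_rate(5, 163.4)
#> 5/163.4 (30.6 per 1000 PY)

demo   <- make_demo_data(tempdir(), seed = 1)
cohort <- read_cohort(demo$cohort)
tab    <- rate_table(time_years(cohort), cohort$event,
                     rows = cohort$morphology,
                     cols = bin_volume(cohort$volume_cm3))
subset(tab, row == "diffuse")
#>        row   col events person_years rate_per_1000py
#> 2  diffuse   <20      1        602.3        1.660302
#> 5  diffuse 20-40      5        335.9       14.885383
#> 8  diffuse   >40      5        163.4       30.599755
#> 11 diffuse   All     11       1101.6        9.985476
```

Among diffuse nidi the hemorrhage rate climbs steeply with volume (1.7 →
14.9 → 30.6 per 1000 person-years below 20, between 20–40, and above
40 cm³), while the whole cohort's 14 events in 1717.5 person-years give an
annualised rate of 0.8%/yr — well under the 2.2%/yr natural course.

`run_pipeline()` chains everything — segmentation of a set of cases, rate
tables, Kaplan–Meier/log-rank against the simulated natural course, and a
backward-selected Cox model — into a single seeded, hash-stamped JSON
report. See the methods vignette (`vignettes/compactness-and-hemorrhage.Rmd`)
for the modelling details and design choices.

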