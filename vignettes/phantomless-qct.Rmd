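---
title: "Phantom-less QCT bone densitometry: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-less QCT bone densitometry: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plqct)
```

## The measurement problem

Millions of chest CT scans are acquired every year for lung-cancer or
COVID-19 screening. Each of them images the thoracic spine for free, so the
volumetric bone mineral density (vBMD, mg/cc) of vertebral trabecular bone
can be measured opportunistically, without extra radiation, and used to
screen for osteoporosis. Two obstacles stand in the way. First, CT voxel
values (Hounsfield units, HU) are not absolute: two scanners imaging the
same bone return different HU, so raw attenuation cannot be compared across
devices. Conventional quantitative CT (QCT) solves this by scanning a
calibration phantom of known densities with the patient, which brings
logistics, beam-hardening and scatter problems of its own. Second, manual
placement of regions of interest (ROIs) does not scale to screening volumes.

`plqct` implements the phantom-less alternative: two tissues present in
every chest scan — subcutaneous fat and paraspinal muscle — serve as the
internal calibration references, and all ROI placement is automatic and
deterministic.

## The calibration model

Let $H_f$ and $H_m$ be the measured mean HU of fat and muscle, and
$\rho_f$, $\rho_m$ their assigned equivalent densities in mg/cc. The
calibration is the exact two-point line

$$\mathrm{vBMD} = a\,H + b, \qquad
  a = \frac{\rho_m - \rho_f}{H_m - H_f}, \qquad
  b = \rho_f - a H_f,$$

applied to the trabecular ROI mean $H_t$. Because both anchors are measured
in the same scan with the same scanner, any affine distortion of the HU
scale (the dominant inter-device difference) cancels: if a device reports
$H' = sH + o$, then all three of $H_f, H_m, H_t$ transform together and the
estimated density is unchanged. This device invariance is the central
property of the method and is tested directly (two simulated devices with
different HU responses imaging the same true density must agree to
< 2 mg/cc).

The reference densities $\rho_f = -50$ and $\rho_m = +40$ mg/cc are
configuration constants (`calibration$rho_fat_mgcc`,
`calibration$rho_muscle_mgcc`), in the range used for fat/muscle internal
references in the phantom-less QCT literature. They are deliberately
explicit and swappable rather than baked in: any error in them acts as an
affine miscalibration of the output scale, identical for all scanners, and
the synthetic device models are constructed consistently with whatever
values are configured so that end-to-end recovery of simulated truth is
exact. Whether reference densities should be age- or sex-adjusted is an
open question we do not attempt to answer; the defaults are global.

A calibration with muscle-fat contrast below 10 HU
(`calibration$min_tissue_contrast_hu`) is rejected as degenerate — the
slope becomes numerically unstable long before that, so the threshold is
conservative. Negative computed vBMD (possible for pathologic inputs) is
reported with a `negative_vbmd` flag, never clamped, because clamping would
silently bias cohort statistics.

## Automatic ROI placement

The published system derives its ROI automation from a trained model that
is not reproducible from the description; `plqct` substitutes deterministic
threshold-and-morphology heuristics with every window and margin exposed in
`plqct_config()`. The intent is exact reproducibility and testability, not
anatomical sophistication.

**Vertebral localization.** Bone is thresholded at
`roi$bone_hu_threshold = 200` HU inside a posterior midline corridor
(half-width `roi$corridor_halfwidth_mm = 45` mm). Slices are scanned for
bone area; contiguous runs of slices with area above
`roi$min_bone_area_mm2 = 50` mm² are vertebral bodies, separated by disc
gaps (the between-body minima of bone area). Bodies are counted caudally
from the most cranial *fully imaged* body — a run touching the top of the
volume is partial and is skipped, mirroring the clinical exclusion of scans
that cut off the target level. The mid-body slice is the median slice of
the run; the in-plane center is the bone centroid there. When two candidate
runs are otherwise equivalent the more caudal one is chosen, a
deterministic tie-break.

**Trabecular ROI.** A circle grown from the mid-body center, with radius
set by the distance to the nearest cortical-level voxel
(`roi$cortical_hu_threshold = 400` HU) minus a safety margin
(`roi$margin_mm = 3` mm), evaluated over all slices of the span. This
guarantees — by construction, and audited against phantom masks in the
tests — that no ROI voxel lies within the margin of the shell, where
partial-volume blending with cortical bone would inflate the density. The
craniocaudal span is `floor(9 mm / slice thickness)` slices (minimum 1), so
the sampled bone volume is comparable across 1, 3 and 5 mm protocols
without resampling; volumes are never interpolated, because interpolation
would mix compartments and bias densitometry.

**Fat and muscle ROIs.** Candidate masks come from HU windows
(fat $[-190, -30]$, muscle $[10, 100]$), intersected across the slice span
and restricted anatomically: muscle to the two paraspinal regions posterior
to the vertebral centroid and within 60 mm of the midline; fat to the
subcutaneous band within 30 mm of the skin surface (the skin is found as
the boundary of the air component connected to the image border, which
distinguishes outside air from lung). Each region's largest
morphologically-opened component receives its largest inscribed
axis-aligned ellipse, shrunk by `roi$inscribe_scale = 0.8` to stay clear of
fascia and partial-volume edges. Muscle HU is the mean of the left and
right ROI means; an asymmetric pair is tolerated but the symmetric average
damps lateralized noise.

**ROI statistics.** ROI means are trimmed means: `roi$trim_fraction = 0.05`
of voxels are dropped from each tail, which removes basivertebral-vein or
streak outliers while leaving a symmetric noise distribution unbiased.
ROIs under `roi$min_roi_voxels = 50` voxels are flagged unreliable.

## Diagnostic classification

QCT categories follow the ACR volumetric thresholds: osteoporosis below
80 mg/cc, normal above 120 mg/cc. The published wording leaves the
endpoints ambiguous; `plqct` assigns both endpoints to osteopenia
(`[80, 120]` closed), a documented and configurable convention. DXA
categories follow the WHO criteria exactly as stated: T ≤ −2.5
osteoporosis, −2.5 < T ≤ −1.0 osteopenia. The clinical composite DXA label
is the minimum of the available site T-scores, as surgeons use in practice;
a record with no site measurement at all is an error rather than a silent
"normal".

## Evaluation statistics

ROC analysis treats *low* vBMD as the positive class and reports the
Youden-optimal "associated criterion" as "≤ c" where c is an attained
score — the largest score still classified positive at the optimum. Ties in
J are resolved toward higher specificity (fewer false positives), then
toward the smaller criterion; both rules are deterministic choices the
underlying data cannot make for us. AUC is computed by the Mann-Whitney
statistic with the 1/2 tie convention (identical to the trapezoidal rule),
and the 95% CI by DeLong's method, with a seeded stratified bootstrap
(`roc$n_boot = 2000`) as a configurable alternative; DeLong is the default
because it is deterministic. The tests verify the AUC against a brute-force
concordant-pair count and the criterion against exhaustive threshold
search, and cross-check AUC and CI against an independent ROC
implementation (pROC).

Precision is the root-mean-square of per-subject standard deviations over
repeat measurements, with CV% = RMS-SD / grand mean × 100 — the standard
densitometric definition. No assumptions are made about the re-scan
protocol beyond "two or more repeats per subject".

Age stratification uses seven decade bins, closed on the left, with open
extremes (`<30`, `80+`); empty bins report n = 0 and an undefined (never
zero) mean. Demographic summaries use the sample SD (n − 1), and the pooled
mean over all records equals the count-weighted mean of subgroup means — an
identity the tests exercise against the published subgroup/total
arithmetic.

## What the synthetic data emulates — and what it does not

The patient scans behind the published evaluation are IRB-restricted, so
the package ships a generator for every input it needs.

**Phantom.** An axial chest section: air background, two lung fields
(−800 HU), soft-tissue thorax (0 HU), a subcutaneous fat band thicker
posteriorly, two paraspinal muscle ellipses, and a vertebral-body cylinder
with a 3 mm cortical shell (800 HU) around a trabecular core. The core HU
is the device line evaluated at the true density; fat and muscle HU come
from the same line at the configured reference densities. Noise is
additive, Gaussian, independent per voxel. The manifest records the truth
(density, device line, compartment masks, body centers), so every pipeline
stage can be scored without re-deriving anything.

Real chest CT differs in ways the phantom deliberately ignores: soft tissue
is set to 0 HU so the muscle HU window cannot leak into it (real muscle and
viscera overlap in HU and are separated by location, which the anatomical
restrictions emulate only coarsely); there is no beam hardening, scatter,
streak, marrow-fat gradient, basivertebral vein, osteophyte or aortic
calcification in the image; vertebral bodies are perfect cylinders. Passing
phantom tests therefore demonstrates the *geometric and algebraic*
correctness of localization, ROI placement and calibration — not robustness
to real anatomy, which only real scans can show. This is the honest scope
of desk-scale validation.

**Cohort.** Ages are drawn per sex from the demographic means/SDs of a
screening population; true vBMD per record from a normal around its
age-bin/sex mean (SD 25 mg/cc, a typical population spread). The bin means
anchor at 155.19 (women 30–39), 66.59 (women 80+), 161.7 and 72.2 mg/cc
(men), with linear interpolation between and slightly higher values under
30 (160/165 mg/cc, consistent with "about 160 mg/cc below age 30") — so the
generated population declines progressively with age, steeper in women
after the menopausal decades. Observed QCT is truth plus N(0, 5 mg/cc)
measurement error. DXA T-scores are linked affinely so the diagnostic
boundaries coincide (80 mg/cc ↔ T = −2.5, 120 mg/cc ↔ T = −1.0), with
independent per-site noise (SD 0.5 T); this linkage is a modelling
convenience that makes the modalities nominally concordant before
discordance mechanisms are added, not an empirical calibration. The
discordance mechanism is explicit: with probability increasing with age
(4% baseline, +1%/year over 50, capped at 45%), the spine T-score is
inflated by a Gamma(2, 0.5) amount — the osteophyte/vascular-calcification
false-negative mechanism of DXA. On such a cohort QCT flags a higher
osteoporosis proportion than spine DXA, which the tests assert as a
qualitative property.

**Repeat scans** re-render the same subject with fresh noise and a small
Gaussian in-plane repositioning of the whole anatomy (default SD 1 mm),
feeding the precision metrics.

## Numerical and engineering choices

- Voxel indices are 1-based; the slice index increases toward the head;
  rows run anterior→posterior and columns patient-right→left. One fixed
  convention shared by generator, ROI code and manifests removes every
  orientation ambiguity.
- NIfTI is the interchange format (written as float64, so HU round-trip
  bit-exactly); DICOM is read-only input, restricted to axial orthogonal
  explicit-VR little-endian series. Oblique series and inconsistent slice
  spacing (> 10% gap variation) are rejected, not resampled.
- Volumes are HU-normalized exactly once, at load; the tag prevents double
  rescaling.
- Calibration happens once per volume at the measured level (not
  per-slice): the tissue anchors come from the same slices as the
  trabecular ROI, so per-slice calibration would only add variance.
- All randomized procedures (phantom noise, cohort draws, bootstrap) take
  explicit seeds and are bit-reproducible; identical config + seed gives
  byte-identical outputs.
- Degenerate inputs fail loudly with stage-tagged messages (`[locate] no
  spine found`, `[tissue_rois] tissue ROI not found: fat`, ...) rather than
  propagating NaN.

The test suite runs phantoms at 3 × 2 × 2 mm voxels on a
24 × 120 × 120 grid (about 0.3 s per full measurement), 20–30 noisy
replicates per recovery check, and cohorts of 300–2000 records — sizes
chosen so the whole suite completes in well under a minute per file while
leaving Monte-Carlo error far below the tolerances being asserted.

## Known limitations

- The ROI heuristics assume a roughly supine, roughly centered patient;
  severe scoliosis, instrumentation or missing anatomy will defeat the
  corridor and window logic (by design, with errors rather than wrong
  numbers).
- Single-level (T12) measurement only; no multi-vertebra averaging, no
  hip/femur module, no cortical-bone reporting.
- The linear device model captures affine HU differences between scanners;
  kernel-dependent nonlinearity, beam hardening and scatter are outside the
  model (avoiding their worst effects is, precisely, the argument for
  internal calibration).
- Reference equivalent densities are global constants; any bias in them
  shifts the output scale uniformly.

## A worked example

```{r example, eval = FALSE}
library(plqct)

# simulate a subject with known truth, measure, classify
p <- generate_phantom_volume(phantom_spec(true_density_mgcc = 95,
                                          noise_sd_hu = 10, seed = 42))
res <- measure_vbmd(p$volume)
tidy(res)

# cohort-level evaluation
cohort <- generate_cohort(cohort_model(n = 649, seed = 1))
report <- cmd_evaluate(cohort, reference = "spine")
report$roc
autoplot(report$confusion)
plot_age_trend(cohort)
```
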