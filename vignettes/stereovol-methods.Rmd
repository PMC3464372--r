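---
title: "Methods: Cavalieri stereology, precision prediction and in-silico method validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Cavalieri stereology, precision prediction and in-silico method validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereovol)
```

## The problem

Validating an automated volumetry method against a manual gold standard is a
recurring task in neuroimaging. For subcortical structures such as the
thalamus, where gray-white contrast is poor, the accepted manual reference is
design-based stereology: Cavalieri sampling of sections with point counting.
A validation study then asks three statistical questions: how precise is each
manual estimate (predicted coefficient of error), how well do raters and the
automated method agree (intraclass correlation for absolute agreement), and
whether both methods are equally sensitive to a known group difference
(between-group ANOVA on patients with bilateral atrophy vs controls).

Subject MRI data underlying such studies are typically not shared, so
`stereovol` pairs the estimators with a synthetic phantom-cohort generator
that emulates the statistical structure of a two-group validation study. The
estimators run identically on real NIfTI segmentation masks
(`measure_masks()`), with the synthetic observers bypassed.

## Cavalieri estimation with point counting

A binary mask with voxel spacing defines the structure in physical
coordinates. A sampling design consists of parallel sections at positions
`t0 + k d` (section interval `d` mm, start `t0 ~ U[0, d)`) and, on each
section, a square point grid with spacing `u` mm and uniformly random in-plane
offset in `[0, u)^2`. A test point is counted when the voxel containing it
(half-open voxel boxes) is foreground. The volume estimator is

    V = (sum_i P_i) * a_p * d,      a_p = u^2

where `P_i` is the point count on section `i`. With uniformly random offsets
this estimator is unbiased for the voxel-count volume of the mask — the
property the test suite verifies by Monte Carlo z-test against phantoms with
closed-form volume.

Defaults are `u = 3.12` mm and `d = 1` mm, the sampling density of the
validated thalamus protocol; both are configuration values. Anisotropic voxel
spacing is honored because all geometry is computed in mm. Sections covering
the foreground bounding range are all retained in the count record, including
interior zero-count sections, because the precision estimator needs the
serial structure of the series.

## Predicted precision: the Gundersen-Jensen CE

The coefficient of error of a single Cavalieri estimate is predicted from one
count series. With serial sums `A = sum P_i^2`, `B = sum P_i P_{i+1}`,
`C = sum P_i P_{i+2}`:

* point-counting noise: `Noise = 0.0724 (b/sqrt(a)) sqrt(n sum P)`, where `n`
  is the number of sections hitting the structure and `b/sqrt(a)` the profile
  shape coefficient (3.545 for circles; default 4.0 for mildly elongated
  subcortical profiles — the prediction is insensitive to it);
* sampling variance: `Var = alpha(m) (3(A - Noise) - 4B + C)`, with
  `alpha(0) = 1/12` and `alpha(1) = 1/240`; the smoothness class `m = 1`
  (default) suits smooth compact bodies like the thalamus, `m = 0` is the
  conservative choice;
* `CE = sqrt(Noise + max(Var, 0)) / sum P`. Negative sampling variance, which
  short noisy series can produce, is floored at zero. With fewer than three
  sections hitting the structure the series carries no usable serial
  information and a noise-only CE is returned with a warning.

### Validity regime and grid re-randomization

The noise term models per-section area errors as independent, which is true
when the grid is repositioned on every section — as on-screen point-counting
software does when a new image is displayed. If instead one grid offset is
reused down the whole stack, the in-plane error of consecutive sections is
strongly correlated: on a thalamus-scale phantom the empirical CE is then
roughly four times the predicted CE, while with per-section re-randomization
prediction and empirical CE agree within a factor of about 1.5 (the accepted
stereological tolerance is a factor of 2). For this reason:

* `empirical_ce()` re-randomizes the grid per section by default;
* `run_study()` rater designs re-randomize per section
  (`study_config(resample_per_section = TRUE)`), emulating on-screen counting;
* `make_design()` keeps a single offset per subject as its default for
  standalone estimation, with `resample_per_section` exposed.

`optimize_density()` implements the standard protocol-tuning step: walk a
coarse-to-fine ladder of candidate designs and accept the coarsest whose mean
predicted CE meets the target (5% in the emulated protocol). Designs that
miss the structure entirely are dropped from the average, as a pilot count
would be repeated.

## The phantom-cohort generator

**Phantoms** are superellipsoids `|x/a|^p + |y/b|^p + |z/c|^p <= 1`
(default axis ratios 1.5 : 1 : 0.8, exponent 2.5, random orientation),
chosen over atlas-derived meshes because the closed-form volume
`8abc Γ(1+1/p)^3 / Γ(1+3/p)` provides the analytic oracle that unbiasedness
tests require. Semi-axes are rescaled so the analytic volume equals each
subject's true volume exactly. An optional smooth radial bump deformation
breaks the symmetry for robustness experiments.

**Cohorts** follow the study population the package emulates: 62 controls and
10 patients with bilateral thalamic atrophy; per-hemisphere true volumes are
drawn from the group means and SDs reported for the manual method (controls
7507.8 (805.6) / 7482.6 (767.2) mm^3, patients 6843.2 (746.6) / 6763.3 (824.0)
mm^3, left/right), truncated at zero (negligible at these parameters but
guaranteed). Left and right volumes are correlated at 0.7 — a modeling choice
for realistic asymmetry scatter, not a reported value; the observed left-right
mean difference remains near zero, as in the emulated study.

**Observers.** Raters are mask-level processes: the phantom surface is
displaced by a spatially smooth radial Gaussian field (correlation length
5 mm along the surface, random-Fourier-feature construction, truncated at
±5 SD so the displacement is provably bounded), then scaled for fractional
volume bias; the perturbed shape is rasterized and point-counted like any
real segmentation. Spatial smoothness matters: human boundary disagreement is
coherent across neighbouring sections, not independent voxel noise. The
automated method is a volume-level observer (bias plus additive Gaussian
noise) by default, since re-implementing an atlas segmentation pipeline is
out of scope; a mask-level mode exists for spatially explicit experiments.

### Observer calibration

The emulated study reports agreement coefficients but no direct measurement
of boundary noise, so observer noise magnitudes are free parameters
calibrated against the reported 10-subject pairwise ICCs (0.977 rater-rater,
0.969 and 0.925 rater-automated). Two findings shape the defaults:

* Those three targets are mutually infeasible under any independent
  additive-noise triple: solving the three agreement equations for the three
  noise variances yields a negative variance for rater 1. Calibration is
  therefore necessarily best-fit; `calibrate_observers()` minimizes squared
  distance over a grid and reaches all targets within ±0.05 in expectation.
* Monte Carlo on the mask-level chain gives volume-noise equivalents of
  ~81 mm^3 for 0.15 mm boundary SD and ~169 mm^3 for 0.33 mm, plus ~90 mm^3
  of point-counting noise at the default density.

Defaults: rater 1 boundary SD 0.15 mm, rater 2 0.33 mm, automated volume SD
230 mm^3 with a -0.5% bias (automated segmentation tends to report slightly
smaller mean thalamic volumes). The volume-level equivalents (120, 190,
230 mm^3) in `volume_level_observers()` make large replicate ensembles cheap.

## Study pipeline and statistics

`run_study()` chains generator, observers and estimators, then computes:

* the pairwise ICC matrix (rater1/rater2/automated, per hemisphere) on 10
  randomly selected controls — ICC(A,1), the single-measure two-way
  absolute-agreement form, `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
  with McGraw-Wong F-based confidence intervals. The same mean-squares
  formula serves the two-way random and mixed models; the choice affects
  interpretation, not the estimate. Degenerate tables (zero between-subject
  variance) are flagged, not silently computed.
* whole-sample ICCs between rater 1 and the automated method, patients and
  controls pooled (the pooled n = 72 design of the emulated study);
* left-right ANOVA per method and the between-method comparison of the signed
  asymmetry index `100 (L - R) / ((L + R) / 2)` (the study reports the
  asymmetry comparison without stating its formula; this signed percentage
  index is a documented choice);
* patient-control one-way ANOVAs per method and hemisphere, Bonferroni
  adjusted over the four contrasts by default (the emulated study corrected
  for multiple comparisons without naming the procedure; Holm is available).

Every stochastic stage draws from a stream derived from the master seed by a
documented splitting rule (`child_seed()`), so a report is regenerable
bit-identically from config plus seed and the user's RNG state is never
touched.

`replicate_sensitivity()` repeats the study across many cohorts (volume-level
observers by default) and summarizes how often the manual and automated
methods agree on detecting the group difference at `alpha = 0.05` in both
hemispheres. At the default study conditions the two methods agree in roughly
85-90% of replicate cohorts, with per-method rejection rates of about
0.6-0.8 — the atrophy effect (~660 mm^3 against an SD of ~800 mm^3 with only
10 patients) is detectable but not saturated, so single-study significance is
expected to vary while the two methods, which measure the same subjects,
track each other closely.

## Numerical choices and problem sizes

* Rasterization tests voxel centres; at 1 mm voxels a thalamus-scale phantom
  is within ~0.5% of its analytic volume, and mean absolute error (averaged
  over generic orientations) decreases monotonically at 1.0, 0.5, 0.25 mm.
  Axis-aligned orientations can show non-monotone error at coarse voxels
  because symmetry cancels the leading error term.
* Superellipsoid evaluation is restricted to the bounding sphere and the
  noise field to a band around the surface (width set by the ±5 SD field
  truncation), keeping a full 72-subject mask-level study around half a
  minute.
* Connectivity is verified by 6-neighbour flood fill on the cropped bounding
  box; an observation that disconnects the mask is retried with a fresh seed
  up to five times before erroring.
* Test and validation ensembles use 50-1000 random designs, 200-400 CE
  replicates, 200 replicate cohorts and 60-80 calibration replicates: sizes
  at which the Monte-Carlo error of each checked quantity is several times
  smaller than the tolerance being asserted.

## What passing tests do and do not show

The generator reproduces the *statistical* structure of a validation study:
group means and SDs, observer agreement levels, estimator precision, and the
power of the group comparison. It does not reproduce thalamic anatomy, MR
contrast, intensity inhomogeneity, partial-volume effects, or the spatially
structured errors of a real segmentation algorithm; geniculate bodies and
subnuclei are likewise out of scope. Passing tests therefore demonstrate the
correctness and calibration of the estimators and statistics, and the
internal consistency of the emulated study — not the field performance of any
particular segmentation tool. Reported ICC values from a single simulated
study scatter around their expectations (n = 10 agreement tables are noisy);
only expectations over replicates are calibrated.
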