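---
title: "Quantifying and classifying venous reflux from cine phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying venous reflux from cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinflow)
```

## The problem

Venous reflux of the lower extremities is retrograde (toward-foot) flow
caused by incompetent venous valves, most often in the superficial system
drained by the great saphenous vein (GSV). Cardiac-gated phase-contrast MRI
measures the through-plane velocity of every pixel in a vessel cross
section at each phase of the cardiac cycle without contrast agents. Summing
velocity times pixel area over a lumen ROI gives a signed flux curve per
beat; its antegrade and retrograde lobes quantify the reflux directly.

`veinflow` implements the complete chain: a synthetic cine generator with
analytic ground truth, the per-ROI flow quantification, assembly of a
six-feature classifier input per subject, a radial basis function neural
network (RBFNN) classifier, confusion-matrix metrics, and per-segment
group statistics. This vignette records the model, the tunable parameters,
and the design choices made where the design was genuinely open.

## Flow quantification

`compute_flux_curve()` sums the phase-shift signal over ROI pixels:
flux in mL/s when velocities are cm/s and pixel areas cm². The sign
convention is toward-head positive everywhere and is stored in the cine
metadata.

`compute_qflow()` integrates the flux over one R–R interval by the
trapezoid rule on the cyclic phase grid (each phase weighted by half the
span between its neighbours, the last interval closing the cycle). Phases
with positive net flux accumulate the forward flow volume (FFV), negative
phases the backward flow volume (BFV); stroke volume SV = FFV − BFV,
absolute stroke volume ASV = FFV + BFV, regurgitant fraction
RF = 100·BFV/FFV, mean flux MF = SV·HR/60, stroke distance SD = SV/area,
mean velocity MV = SD·HR/60.

Three numerical choices deserve a note:

* **Direction split at the phase level.** Vendor-style flow reports show a
  single signed flow sequence per vessel, so the forward/backward split is
  made on the sign of the net ROI flux per phase. A per-pixel split (each
  pixel's velocity signed before summation) is available via
  `batch_qflow(split = "pixel")` for sensitivity checks; on noise-free
  laminar profiles the two agree exactly.
* **RF with zero FFV is `NA`,** never a silent number: a regurgitant
  fraction has no meaning without forward flow, and silent zeros would
  corrupt downstream statistics.
* **SD is computed as SV divided by the ROI area.** The "net distance
  blood travels per beat" equals net volume over lumen cross-sectional
  area; this also makes MV·area = MF hold as an exact identity, which the
  test suite asserts to 1e-9.

## The synthetic generator

Real scans of this kind are not publicly available, so the generator is a
first-class, tested component that defines the study conditions: 26 limbs
with superficial GSV reflux and 15 healthy-control limbs (one limb per
subject), each with cines at the four setpoints EIV, FV, PV, GSV; 30
cardiac phases on a 64×64 grid at 0.17 cm pixel spacing (the 1.7 mm
in-plane voxel of lower-limb QFlow protocols); heart rates Normal(70, 8)
truncated to 40–120 beats/min.

### Waveform family

Venous flow is only weakly pulsatile, so each vessel's flux over one cycle
is piecewise sinusoid-plus-constant: a constant baseline (`mean_flux`,
mL/s), a half-cycle sin² antegrade pulse, and — in refluxing GSVs only — a
reflux window in which the antegrade flow closes down over exactly one
phase bin (cos² taper, emulating valve closure), reverses as a sin²
retrograde lobe, and reopens. The lobe amplitude is set so its integrated
volume equals `reflux_fraction` times the integrated antegrade volume,
hence BFV = reflux_fraction · FFV exactly and all truth volumes are closed
form.

All window junctions are snapped to the sampled phase grid and every piece
has vanishing end derivatives. By the Euler–Maclaurin expansion the cyclic
trapezoid sum of such a curve equals its integral essentially to machine
precision, and the sign split is clean because flux changes direction
exactly at sampled phases where it is zero. Noise-free rendered cines
therefore reproduce the analytic truth to rounding error — the 0.5%
round-trip tolerance in the tests is satisfied by construction, not by
luck. The price is a mild idealization: real reflux onsets do not align
with the acquisition grid. Since the quantification never uses that
alignment, only the truth bookkeeping does, this does not favour the
method under test.

### Spatial rendering

Inside the lumen the velocity profile is parabolic (Poiseuille), scaled
each phase so that the in-lumen pixel flux sums exactly to the waveform's
flux; only the area-integrated flux matters downstream, so the profile
shape is immaterial. Zero-mean Gaussian velocity noise (default SD 1 cm/s)
is added over the whole frame. The ROI mask is the set of in-lumen pixels,
and ground-truth SD/MV/RF use the discrete mask area — the ROI is the
mask, and the quantification divides by the drawn-contour area.

### Group effect structure

The between-group effect is confined to the GSV: reflux limbs draw a
reflux fraction from a truncated Normal(0.5, 0.12) on [0.2, 0.8] and
carry a baseline-flux multiplier of 1.85. The multiplier models the
dilated, high-throughput refluxing GSV; numerically it means the expected
antegrade volume still rises by ~35% after subtracting the antegrade flow
suppressed during the reflux window, giving the intended qualitative
signature — FFV and ASV up, SV and MF down — while EIV/FV/PV parameters
are drawn from distributions shared between groups. Between-subject
spread is log-normal (sdlog 0.25) on each vessel's baseline flux. No
numeric flow values per vessel are published for this setting, so these
magnitudes are calibrated to the qualitative significance pattern
(GSV discriminates, the other segments do not), not to printed numbers.

`null_cohort_config()` removes the effect entirely (shared GSV
distributions, no retrograde lobe) and is used to calibrate the type-I
error of the group comparisons: over 500 simulated null cohorts the
pooled-t rejection rate at α = 0.05 must lie in 0.05 ± 0.02.

### What the generator does not emulate

No k-space physics, no phase wrapping or velocity-encoding artifacts, no
ECG-trigger jitter, no eddy-current or background-phase offsets, no
vessel-segmentation error (masks are exact). Passing tests demonstrate
the correctness of the quantification and classifier machinery under
controlled conditions, not robustness to scanner artifacts.

## Feature construction

Per subject the classifier input is (SV, FFV, ASV, MF at the GSV;
GSV/PV ratio of SD; GSV/PV ratio of MF), with label 1 for reflux limbs.
Two open choices:

* **The second ratio defaults to MF,** matching the feature list used for
  the classification experiment; `ratio = "mv"` substitutes the MV ratio,
  which the surrounding discussion of prior work suggests as an
  alternative. Both are supported because the source description is
  internally inconsistent; the default follows the explicit feature list.
* **Standardization is on by default.** The six features mix mL, mL/s and
  unitless ratios inside one Euclidean distance; without scaling a single
  unit would dominate ‖x − μⱼ‖. Scaling uses the population (1/n)
  standard deviation so that a two-point training set maps to ±1 and the
  shared RBF width of standardized features is exactly 1.
  `standardize = FALSE` mimics the unscaled formulation literally.

Subjects with a missing GSV/PV row or a zero PV denominator are excluded
with a logged reason rather than silently dropped or propagated as
non-finite features.

## The RBFNN

Hidden units are Gaussians φⱼ(x) = exp(−‖x − μⱼ‖²/2σ²); the output is the
plain linear combination y(x) = Σⱼ wⱼ φⱼ(x) with no bias term. Defaults
and their rationale:

* **k = 16 hidden units** — the configuration reported as optimal for
  this task.
* **Centers by Lloyd's k-means** from a seeded random sample of k distinct
  training points, at most 100 iterations, empty clusters re-seeded to the
  point farthest from its center. Initialization from data points keeps
  centers inside the training bounding box and makes the fit reproducible
  from a single seed.
* **σ is a single scalar**: the standard deviation of the input vectors,
  sqrt(mean ‖xᵢ − x̄‖²/p). The phrase "standard deviation of the input
  vectors" is ambiguous between a scalar, per-dimension widths, and
  per-center widths; the scalar reading is the default and the width is
  overridable (`sigma =`).
* **Weights by normalized LMS**: w ← w + η/(ε + ‖φ‖²)·(d − wᵀφ)·φ with
  η = 0.5, ε = 1e-6, zero initialization, per-epoch shuffling. The
  energy normalization makes the rule stable for η ∈ (0, 2), which the
  tests verify as a per-sample non-amplification property.
* **Epochs default to 1000.** On the 41-sample, 16-unit kernel system a
  few hundred passes leave the output layer visibly under-converged
  (erratic score ranges and training misclassifications attributable to
  optimization rather than class overlap); by ~1000 passes the per-seed
  training metrics stabilize. The per-epoch MSE trace is stored on the
  model for inspection. Note that fixed-step NLMS retains a steady-state
  misadjustment proportional to η; where a test needs agreement with the
  normal-equations least-squares optimum it uses a small step
  (η = 0.05), under which the final MSE lands within a few percent of
  the optimum.
* **Decision rule is strict**: positive iff y(x) > threshold. The
  threshold is either fixed (0.5, the reported operating point) or swept
  over {0, 0.01, …, 1} to maximize the training F-measure, ties broken
  toward the smallest threshold; thresholds predicting no positives score
  F = 0 (the limit of the harmonic mean as recall → 0).

The training protocol deliberately mirrors a training-stage report: all 41
subjects are used for training and the same 41 are evaluated. This
overstates generalization by construction; `run_pipeline()` makes no
held-out claim, and the metrics it reports are training-stage figures.

## Group statistics

`compare_segments()` runs the classic pooled-variance unpaired two-tailed
Student's t test (Welch's form behind `welch = TRUE`) for each of SV, FFV,
ASV, MF, SD, MV in each of the four segments — 24 tests, reported raw.
No multiple-testing correction is applied, matching the reporting style
this mirrors; the printed table notes that p-values are uncorrected.
Degenerate inputs follow explicit contracts: both samples constant and
equal gives t = 0, p = 1; constant but unequal is rejected as undefined.

## Problem sizes used by the tests

The acceptance suite runs the full-size conditions: one noise-free
rendered cohort for the round-trip check; 20 rendered cohorts
(26 + 15 subjects, 164 cines each) for the classification analogue, whose
median training accuracy/sensitivity/precision are also what
`scripts/acceptance.R` reports; and 500 waveform-level null cohorts for
the type-I calibration. Unit tests use a 10-subject cohort on a 32×32
grid to keep the default test run fast. Waveform-level cohorts
(`render = FALSE`) skip pixel rendering — and therefore carry no
measurement noise — which is appropriate for the calibration study, where
between-subject variation dominates.

## Known limitations

* Synthetic effect sizes are qualitative calibrations, not published
  magnitudes; absolute flow values should not be read as normative.
* One limb per subject: the three-group comparison (patients' morbid limb,
  patients' normal limb, controls) collapses to two groups here.
* Training-set evaluation only; no cross-validation protocol is provided.
* The generator's grid-aligned reflux windows idealize the timing of flow
  reversal relative to the acquisition grid.
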