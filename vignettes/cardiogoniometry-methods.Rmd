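---
title: "Cardiogoniometry with cgmr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiogoniometry with cgmr: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmr)
library(dplyr)
```

## The method in brief

Cardiogoniometry (CGM) is a vectorcardiographic technique: instead of
inspecting twelve scalar ECG traces, it reconstructs the *heart vector* —
the instantaneous net electrical dipole of the myocardium — millisecond by
millisecond from five bipolar leads recorded with four thoracic electrodes
plus a ground. The vector traces closed 3D loops during atrial
depolarisation (P), ventricular depolarisation (QRS, called the R loop) and
repolarisation (T). Scalar parameters of those loops — spatial angles,
amplitudes, shapes, octant occupancy, velocities, beat-to-beat variability —
are compared against stratified reference intervals, and a recording is
called *positive* (pathological) as soon as any parameter of the active set
leaves its interval. `cgmr` implements that chain end to end, together with
the synthetic-data generators and the diagnostic-accuracy arithmetic needed
to evaluate such a test against gatekeepers like ECG and troponin in a
chest-pain cohort.

## Electrode geometry and the orthogonal projection

The electrode construction is scale-free: with `d` the distance from the
apex electrode (point 1, at V4) to the dorsal electrode (point 2, at V8),
point 3 sits `0.7 d` above point 1 and point 4 sits to the subject's right
of point 3 at that same distance. The five leads are potential differences:
D = 4−2, A = 4−1, I = 2−1, Ho = 4−3, Ve = 3−1, which forces the identities
`I = A − D` and `Ve = A − Ho`.

Two planes organise the reconstruction. Electrodes 4–2–1 span the *oblique
sagittal plane* (OSP), roughly aligned with the heart's long axis;
electrodes 4–3–1 span the frontal plane. `derive_basis()` builds an
orthonormal X/Y/Z triple from these planes with the anatomical sign
conventions: +X posterior, +Y toward the apex, +Z inferior (negative Z
points up). Orthonormality is exact to 1e-12 by construction for any valid
height ratio.

Two modelling choices here were genuinely open:

* **Projection coefficients.** The commercial device's projection constants
  are unpublished. We associate each lead with the *displacement vector*
  between its electrodes and recover the in-plane heart-vector components
  by least squares over each plane's three leads (OSP: D, A, I; frontal:
  Ho, Ve, A), averaging the two Y estimates. The map is linear,
  numerically exact on consistent leads, and exactly inverted by
  `forward_leads()`; no claim is made that it equals the device's constants
  numerically.
* **Unit versus displacement lead directions.** Projecting on *unit*
  directions would break `I = A − D` exactly, because the three electrode
  separations differ; projecting on displacements (a uniform-lead-field
  model) preserves the potential identities to machine precision, which is
  what the identities' definitional status demands. This is why
  `forward_leads()` uses displacements.

## Beat detection and loop segmentation

The device's detector is undisclosed, so `detect_beats()` is a deliberately
conventional design, declared as configuration rather than science: the
vector magnitude is band-passed 8–40 Hz (4th-order Butterworth, zero-phase),
R candidates are local maxima above half the rolling 2-s maximum with a
250 ms refractory period, and each peak is refined to the raw-magnitude
maximum within ±50 ms. Fiducials are fixed physiologic windows around R
(QRS onset R−60 ms, J point R+60 ms, T offset `min(next R − 240 ms,
R + 450 ms)`, P window R−260..R−90 ms), all tunable in `cgm_config()`.
Recordings faster than 150 bpm or with R-R variation above 20 % CV are
flagged, mirroring the clinical exclusions (tachycardia, non-sinus rhythm);
they are warnings, not errors, because the parameters remain computable.

The ST/T loop starts at the J point (whether the device anchors it at J or
at a fixed offset after J is unknown; the J-based choice is the default and
the window is configurable). Median loops resample each beat's loop to a
common 120-point time-normalised grid and take coordinate-wise medians —
robust to a single aberrant beat by the 4-vs-1 median property, which the
tests assert exactly.

## The parameter catalog

The published taxonomy has six classes; the individual 350 parameters and
their clinically calibrated reference ranges are proprietary. `cgmr`
therefore implements the *framework* with a default catalog of roughly 76
named parameters covering every class:

| class | members | units |
|---|---|---|
| angle | per-loop maximum-vector longitude/latitude; pairwise P/R/T angles | deg |
| amplitude | per-axis minima/maxima; max-vector magnitudes; R/T and P/R ratios; ST level at J+20 ms | mV |
| shape | eccentricity `sqrt(1 − (e2/e1)^2)`, planarity `1 − e3/e1` per loop | – |
| octant | magnitude-weighted fraction of each loop in the 8 sign octants | fraction |
| velocity | max/mean loop speed, R/T mean-speed ratio | mV/s |
| variability | beat-to-beat SD of per-beat max-vector angles (circular SD) and magnitudes | deg, mV |

Conventions fixed here because the source leaves them open: longitude is
`atan2(Y, X)` in (−180, 180], latitude the elevation toward +Z in
[−90, 90]; octant boundary ties go to the positive side; ST is measured
20 ms after J (configurable); `max_vector()` breaks norm ties to the
earliest sample for determinism.

## Scoring and calibration

`score_parameters()` implements the penalty score: zero when every
parameter is inside its closed interval, −1 per out-of-range parameter,
positive CGM iff the score is negative. Bounds are inclusive ("outside the
reference range" is read as strict exteriority). Missing values (degenerate
loops) penalise by default — a fail-safe toward positivity appropriate for
a screening posture — and are reported separately; `na_out_of_range =
FALSE` disables this. The score's magnitude is deliberately not
interpreted: the published method states it carries no severity meaning.

Because the clinical reference ranges are proprietary,
`calibrate_reference_ranges()` builds them from control recordings as
central empirical quantile intervals (linear-interpolation quantiles,
default coverage 99 %). One property matters in practice: with ~76
parameters each covered at 99 %, a *normal* recording still has a
substantial chance of tripping at least one interval, so the raw
false-positive rate of a naively calibrated full catalog is high — the
tests show ischaemic recordings positive at rate 1.0 against a control
false-positive rate well below that, a direction consistent with the idea
that the commercial method uses a *compiled subset* of independent
penalising variables rather than every parameter. Users targeting a
specificity should calibrate on a chosen subset or raise the coverage.

## The synthetic generators

`synth_vcg()` emulates the loop structure of real recordings, not their
full electrophysiology: each beat concatenates three planar ellipses with a
half-sine major-axis envelope (`sin(pi s)` along the configured
maximum-vector direction, `sin(2 pi s)` along a perpendicular minor axis),
so the configured maximum vector is attained exactly at mid-loop whenever
the axis ratio stays below `1/sqrt(2)` (validated at 0.7). Defaults are
chosen to resemble adult sinus beats: QRS 1.2 mV / 100 ms, T 0.4 mV /
250 ms, P 0.15 mV / 110 ms, heart rate 60 bpm, 12 s at 1 kHz, with the
first R peak at 0.3 s and intra-beat timings compressing proportionally
once R-R drops below 0.8 s (so beat count tracks rate × duration within ±1
across 40–150 bpm). Noise is isotropic Gaussian. What this generator does
*not* emulate — respiratory drift, electrode noise spectra, ectopy,
conduction abnormalities, realistic P/T morphology variation — bounds what
green tests mean: they validate the pipeline's arithmetic and its recovery
of known ground truth, not clinical performance on patients.

`apply_ischaemia()` perturbs a configuration along three axes at once,
scaled by a severity in [0, 1]: the T axis rotates away from R (up to 60°),
the R/T magnitude ratio grows (up to +2), and an ST offset appears opposite
the R direction (up to 0.15 mV, ST-depression-like). The ST offset is
applied as a plateau over the ST segment tapering out before the T loop, so
it is measurable at J+20 ms without contaminating the T maximum vector —
otherwise the configured angle shift would not be recoverable.

`synth_cohort()` generates binary test results with specified
sensitivity/specificity per test and a single latent severity per patient
coupling the tests through a probit link with strength `rho` (0 =
conditional independence). The shipped `cohort_spec_table2()` carries the
published admission-test marginals (ECG 0.28/0.78, first troponin
0.34/0.98, serial troponin 0.50/0.96, CGM 0.69/0.54) with `rho = 0.3` as a
realistic default — the admission tests all track disease severity, so some
positive dependence is the plausible regime; the marginals are unaffected
by `rho`. `cohort_table2()` is different in kind: a *deterministic* 216-row
cohort whose joint distribution is the minimal completion consistent with
every published margin (per-test counts, the 106-patient
gatekeeper-negative subgroup with 42 extra true positives and 17 false
positives, and the 28 cases missed by both CGM and first troponin that pin
the 83 % OR-combination). The unprinted joint cells are synthetic and
documented as such.

## Evaluation arithmetic

`metrics()` reports each accuracy measure as an exact fraction plus the
integer percent under half-up rounding, which reproduces every printed
count/percent pair of the published overall-cohort table. `mcnemar_test()`
offers the exact binomial variant (doubled smaller tail, capped at 1) and
the continuity-corrected chi-square, switching at `b + c = 25` by default
since the published analysis names the test but not the variant.
`categorical_test()` uses Pearson's chi-square without continuity
correction unless an expected cell is ≤ 5, where it switches to Fisher's
exact test. `screening_yield()` computes the triage numbers: within the
gatekeeper-negative subgroup, NNT = subgroup size / additional true
positives and NNH = subgroup size / false positives, half-up to one
decimal.

Three cells of the published *subgroup* table are internally inconsistent
(their printed percent does not equal their printed fraction under any
conventional rounding); the package's tests assert the values implied by
the printed counts, which are the quantities the arithmetic actually
determines.

## Numerical choices and problem sizes

All tolerances are stated where they bind: basis orthonormality 1e-12;
forward/inverse round trip 1e-9 relative over 1000 seeded random
trajectories; generator recovery 5 % in magnitude and 2° in angle on
noise-free synthetics; Monte-Carlo recovery of cohort operating
characteristics ±0.01 at n = 20 000 per group. Every stochastic entry
point requires an explicit seed and is bit-reproducible given it. The
end-to-end calibration runs in the tests use 200 control recordings at
250 Hz / 8 s — the quantile calibration and classification behaviour do not
depend on the nominal 1 kHz / 12 s acquisition format, and the smaller
recordings keep the default test run brisk.

## Worked example

```{r example}
sim <- synth_vcg(vcg_config(heart_rate = 60, seed = 42))
params <- extract_all(sim$trajectory)
params |> filter(name %in% c("R_max_magnitude", "T_max_magnitude",
                             "angle_RT", "R_eccentricity"))

ranges <- reference_ranges(tibble::tibble(
  stratum = "sinus", name = params$name,
  low = pmin(params$value, 0) - 1, high = pmax(params$value, 0) + 1))
glance(score_parameters(params, ranges, "sinus"))
```

## Known limitations

* The projection constants, the 350-parameter list and the clinical
  reference ranges of the commercial system are unpublished; this package
  implements the published *framework* with configurable stand-ins and
  claims no numerical equivalence with the device.
* The detector and fiducial windows are conventional choices validated
  against the generator's ground truth only; real recordings with ectopy,
  atrial fibrillation, bundle-branch block or paced rhythms are outside
  the validated envelope (they are flagged, not handled).
* Clinical accuracies (e.g. a 69 % sensitivity for NSTE-ACS) depend on
  patient data that were never deposited; the package reproduces the
  published arithmetic and evaluates the method on synthetic data, nothing
  more.
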