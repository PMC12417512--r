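---
title: "Electrographic flow mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrographic flow mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egflow)
```

## The problem

In persistent atrial fibrillation (AF), wavefronts that sustain the
arrhythmia often arise from localized extra-pulmonary-vein sources —
focal sites from which activation diverges, or rotors around which it
circulates. Electrographic flow (EGF) mapping estimates the atrial
activation velocity field from 60-second, 64-channel unipolar
electrograms recorded with an 8-spline × 8-electrode basket catheter
sampled at 1 kHz, and searches that field for persistent flow
singularities. Sources that are detected in a large fraction of the
recording, at sufficient quality-adjusted activity, have been associated
with post-ablation AF recurrence; `egflow` implements the full chain
from raw electrograms to those clinical quantities, together with a
ground-truth simulator and an outcome layer, so that every stage is
testable without patient data.

## Geometry

The basket is represented as a cylinder: spline letters A–H map to a
periodic axis ($A = 0, \dots, H = 7$, wrapping at 8) and electrode
numbers 1–8 to a clamped axis ($1 \to 0, \dots, 8 \to 7$), with
electrode 1 taken as the distal row. Whether the clinical labelling
starts distally or proximally is not standardized across systems; the
orientation here is a documented package convention, and all detection
results are equivariant to rotations of the spline axis (this is a
tested property). Region labels follow the field's two-letter/two-digit
convention: `"DE45"` is the midpoint of splines D–E and electrodes 4–5,
i.e. grid position (3.5, 3.5); letter midpoints are computed on the
periodic axis, so `"HA2"` is (7.5, 1).

## Signal model and preprocessing

Unipolar atrial electrograms are modelled as trains of short biphasic
deflections riding on baseline drift, broadband noise, and a far-field
ventricular (QRST) component that is coherent across the basket.
Preprocessing proceeds in this order:

1. **Drift removal** (`highpass_detrend`): a zero-phase spectral
   high-pass at `highpass_hz` (default 0.5 Hz) applied to the even
   (mirror) extension of each channel. The spectral form was chosen over
   a Butterworth `filtfilt` because at such low cutoffs the IIR filter
   rings at the recording edges and reshapes the passband on every
   application; the spectral operator is exactly idempotent, which the
   pipeline's "preprocessing twice changes nothing" invariant requires.
2. **Ventricular event detection** (`detect_ventricular_events`): the
   cross-channel median suppresses spatially incoherent atrial activity;
   the median trace is band-passed to 3–25 Hz (the QRS band — atrial
   deflections are substantially narrower) and peaks are accepted above
   `qrst_detect_mad` robust SDs *and* an absolute floor of
   `qrst_min_amp_mv` (default 0.1 mV), with a 200 ms refractory period.
   The absolute floor matters: in recordings without ventricular
   far-field, the MAD of the median trace collapses and a purely
   relative threshold would hallucinate events from atrial leak-through.
   Low-amplitude repolarization (T-wave) peaks are rejected by requiring
   peaks to reach 45 % of the 90th-percentile candidate amplitude.
3. **QRST subtraction** (`subtract_qrst`): an event-locked average
   template over −100…+400 ms is subtracted at every event. Template
   subtraction (rather than blanking) preserves atrial content inside
   the ventricular windows. The per-channel template peak-to-peak
   amplitude is retained as the far-field reference for the
   electrode-contact rule. With fewer than `qrst_min_events` (3) events
   the template is statistically unreliable and the recording is passed
   through unchanged with a flag.
4. **Quality assessment** (`assess_quality`): an electrode is admissible
   in a 2-s segment iff its robust near-field amplitude is at least
   `cl_amplitude_ratio_min` (0.7) times its far-field QRST amplitude and
   less than `quality_max_hf_ratio` (0.5) of its RMS lies above
   `quality_hf_cutoff_hz` (100 Hz). The ratio rule is the published
   electrode-contact criterion; the noise rule catches electrodes whose
   far field is attenuated together with the near field.
5. **Normalization** (`normalize_channels`): per-channel division by the
   scaled MAD. A robust scale was preferred to the SD because spike-like
   artifacts dominate second moments.

## Rasterization and optical flow

The 8×8 electrode values are interpolated onto a
`interp_grid`² pixel lattice (default 32², bilinear, periodic in the
spline axis) after temporal Gaussian smoothing (`presmooth_sigma_ms`,
10 ms), resampling to `frame_rate_hz` (50 Hz), and inverse-distance
infill of inadmissible electrodes from admissible neighbours within 2
grid units. Frames are spatially smoothed with a Gaussian of
`presmooth_sigma_px` (1 px). The frame rate is a registered
hyperparameter rather than a constant because the effective temporal
granularity of the clinical system is not published; 50 Hz places a
typical wavefront displacement at ~3 px/frame, inside the regime the
smoothing makes tractable for dense optical flow.

Velocity fields are computed per consecutive frame pair with a classic
Horn–Schunck scheme: brightness constancy plus quadratic smoothness,
minimized by Jacobi iterations (`hs_iterations`, default 100) of

$$u \leftarrow \bar u - I_x \frac{I_x \bar u + I_y \bar v + I_t}
{\alpha^2 + I_x^2 + I_y^2},$$

with central spatial differences on the frame-pair average, a two-frame
temporal difference, periodic boundaries on the spline axis and
replicate boundaries on the electrode axis. The published method is a
proprietary *modified* Horn–Schunck whose modifications are not public;
this package implements the standard scheme and exposes the smoothness
weight, iteration count and pre-smoothing as hyperparameters so that an
optimizer can occupy the same design space. One deliberate addition:
each frame pair is jointly standardized (joint mean subtracted, joint SD
divided out) before the solver, making the flow exactly invariant to
affine intensity changes applied to both frames — without it the
smoothness weight $\alpha$ is not scale-free and flow would depend on
signal gain. The solver is written in C++ (via Rcpp) and is verified
against a dense loop-level R reference implementation to $10^{-6}$.

Fields are vector-averaged over overlapping 2-s segments
(`segment_length_s` = 2, `segment_stride_s` = 1; a 60-s recording gives
59 segments). The 2-s length is the published analysis window; the
overlap is not published and the 1-s stride is a package default.

## Singularity detection and source tracks

A candidate source at position $p$ is scored by sampling the segment's
mean flow at `ring_samples` (16) points on a ring of
`singularity_radius` (2 grid units) around $p$, unit-normalizing each
sample, and averaging its projections onto the outward radial and
tangential unit vectors. The resulting *radial index* and *tangential
(curl) index* are dimensionless and bounded in $[-1, 1]$: an ideal
divergent source scores radial index 1, an ideal rotor $|$curl$|$ 1, and
a uniform (planar) field scores 0 on both. This makes the published bare
"curl ≥ 0.7" rotational criterion interpretable. Candidates are local
maxima of the radial-index field at or above `radial_index_min`, or of
the absolute curl field at or above `curl_rotational` (0.7), followed by
non-maximum suppression and fully deterministic tie-breaking.

`radial_index_min` defaults to 0.85, calibrated on the simulator before
the acceptance studies were frozen: true focal sources score ≥ 0.98 on
2-s mean flow while background-only local maxima have a 99th percentile
of 0.90, so 0.85 keeps essentially all true detections while suppressing
the spurious local maxima that otherwise accrete onto tracks and inflate
prevalence.

Singularities are clustered greedily across segments: each joins the
nearest existing track within `cluster_radius` (1.5 grid units, periodic
metric), else seeds a new track; centroids are circular means on the
spline axis. Per-track quantities:

* **Prevalence** — percentage of segments containing a member
  singularity.
* **Segment detection** — per-frame hit fraction: the ring index matched
  to the track type, evaluated at the centroid on a sliding
  `detection_window_s` (0.5 s) mean of the frame-pair flows, counts a
  hit at `detection_index_min` (0.45). The sliding window is what makes
  a continuously active source register continuously: on instantaneous
  fields the index collapses between wavefront passages and the hit
  fraction would measure wavefront duty cycle instead of source
  presence. 0.45 sits 2.5 robust SDs above the background index
  distribution at a fixed location.
* **Activity** — quality-weighted mean segment detection,
  $100 \sum_s w_s d_s / \sum_s w_s$, where $w_s = 1$ iff the electrodes
  within `cluster_radius` of the centroid are majority-admissible in
  segment $s$. Clinical descriptions of activity — a per-segment
  detection average, normalized and adjusted for electrode contact and
  noise — are verbal rather than operational; this weighted mean
  reproduces its worked numeric examples, reduces to prevalence when all
  segments are admissible and detection is binary, and can exceed
  prevalence when low-quality segments are discounted — matching the
  published example where one source's activity (17 %) exceeds its
  prevalence (15 %).
* **Flags** — *dominant* iff prevalence strictly exceeds
  `prevalence_dominant_pct` (20 %); *significant* iff activity reaches
  `activity_significant_pct` (26.5 %); *rotational* iff the members'
  mean $|$curl$|$ reaches 0.7.

The summary map's per-pixel heat is the fraction of segments with a
singularity within `cluster_radius` of the pixel, so heat maxima equal
track prevalence fractions at the track centroids.

## Cycle length and entrainment

Per-electrode cycle length (CL) is the lag of the highest
autocorrelation peak in `cl_min_ms`–`cl_max_ms` (100–350 ms, the
physiologic AF band), computed on a 4-s window centred on each 2-s
segment — a 2-s window resolves a 300 ms period poorly. Autocorrelation
operates on an activation envelope (band-pass
`cl_bandpass_low_hz`–`cl_bandpass_high_hz` = 40–250 Hz, rectify,
low-pass `cl_envelope_lowpass_hz` = 20 Hz), the classic preprocessing
for atrial CL and dominant-frequency estimation: the autocorrelation of
raw, few-millisecond biphasic deflections is so phase-sensitive that
physiologic jitter alone pushes its peak below any useful admissibility
bar. Electrodes are excluded *before* autocorrelation when their
near-field amplitude is below 0.7× the far-field QRST amplitude
(`low_amplitude`), and after it when the peak falls below
`cl_autocorr_min` = 0.6 (`low_autocorr`). Among near-tied local peaks
(within `cl_peak_tolerance` = 0.05 of the band maximum) the shortest lag
wins: with per-activation jitter the peaks at the true period $T$ and at
$2T$ are stochastically near-equal, and a literal global argmax flips
between them.

Segment statistics (mean CL and sample SD across admissible electrodes;
absent below `cl_min_electrodes` = 8) feed the entrainment contrast:
segments are labelled ON when a track's segment detection reaches
`entrain_on_threshold` (0.5), and the report gives the ON−OFF difference
in median CL, the ratio of median spatial SDs, and the percent SD
reduction. Class aggregates are medians because segments straddling an
ON/OFF switch produce mixed 4-s windows. The report is withheld when
either class has fewer than 3 valid segments.

## Outcome layer

Patients are assigned to four procedural subgroups by comparing
baseline and final maximum source activity to the threshold: both below
→ *no sources*; high→low → *sources ablated*; low→high → *increasing
sources*; both high → *above threshold*. Freedom from recurrence is
estimated by the Kaplan–Meier product-limit estimator (via the
`survival` package, with Greenwood variances) and subgroups are compared
with a landmark Z-test at a fixed horizon,
$Z = (S_a - S_b)/\sqrt{\mathrm{Var}_a + \mathrm{Var}_b}$ with
$p = 2(1 - \Phi(|Z|))$. The published tables say only "Z-test"; the
landmark form reproduces their printed Z→p arithmetic exactly and is
standard for KM comparisons at a fixed time; a log-rank alternative is
available behind `method = "logrank"`. Two printed Z→p rows are
internally inconsistent in their last digit, consistent with rounding of
intermediate values upstream; they are not used as checks.

The activity threshold is recovered from outcomes by cross-validation:
each cycle samples 110 patients without replacement and grid-searches
the cutoff in [5, 60] % (step 0.5) that maximizes the balanced accuracy
of predicting 12-month recurrence from `final_activity ≥ cutoff`; the
returned threshold is the median cutoff over the final 20 % of cycles.
Balanced accuracy was chosen because the published training curves track
specificity and overall accuracy without naming a single objective, and
the recurrence-positive class is the minority; the median-of-tail
aggregation mirrors the published convergence behaviour without
asserting an aggregation rule the source does not state. Only the cutoff
is optimized by default — the same cycle loop can in principle sweep any
registry knob, but a full multi-knob search is outside desk scale.

## The simulator

`simulate_recording` is a phenomenological activation-train generator,
not a reaction–diffusion tissue model. Each electrode carries a train of
30-ms biphasic wavelets. Intrinsic trains have per-electrode cycle
lengths (Normal with `cl_mean_ms`, `cl_spatial_sd_ms`, clamped to
110–345 ms), planar-wave initial phases along a chosen direction, and
per-activation jitter. Sources switch ON/OFF as an alternating renewal
process with exponential dwell times (defaults 4 s ON / 9 s OFF, ON
fraction ≈ 0.3; the cited literature gives random switching but no
dwell distribution — exponential is a modelling choice). While ON, a
source claims electrodes within its `capture_radius` (nearest source
wins on overlap): in `lock` mode they phase-lock to the source's firing
train with a conduction delay of 25 ms per grid unit (focal) or an
azimuthal phase ramp (rotational), collapsing spatial CL dispersion; in
`shift` mode they keep their intrinsic CLs shifted by `delta_cl_ms`,
preserving dispersion — the two modes separate the entrainment
mechanism (SD reduction) from mere rate shifts. Far-field QRST is added
coherently at a regular ventricular rate, plus sinusoidal drift, white
noise, and contact-loss electrodes (near field attenuated ≥ 95 %, noise
and far field retained). Every stochastic draw derives from one seed;
identical configurations are bit-identical.

What the simulator does *not* emulate: meandering source trajectories,
conduction anisotropy and block, electrode motion, epi–endocardial
dissociation, and realistic electrogram morphologies (fractionation,
double potentials). Passing recovery tests on this generator therefore
demonstrates the pipeline's correctness against its own signal model,
not clinical performance on patient data — the latter is outside what
any synthetic study can establish.

`simulate_cohort` draws final activities uniformly, steps the recurrence
probability at a chosen activity threshold, draws event times uniformly
over follow-up, and censors non-events at follow-up; baseline activities
are drawn independently so all four subgroups are populated.

## Problem sizes used in the shipped studies

The packaged acceptance studies use: 20 × 60-s recordings for the
entrainment contrast (intrinsic spatial CL SD 18 ms, driver CL 170 ms
against a 185 ms background, full-basket capture, ±3 ms jitter, 6 s/6 s
dwells); a 200-patient cohort with 50 cycles of 110-patient subsets for
threshold recovery; and 100 × 12-s recordings (15 % rotational, one
always-ON source each) for the rotational-fraction study. Unit and
property tests use 6–16-s recordings and a 3 × 3 (ON-fraction × seed)
grid of 60-s runs for prevalence tracking; these sizes are the package's
desk-scale choices and are stated here so they can be scaled up
deliberately.

## Known limitations

* Activity is one defensible operationalization of an under-specified
  published definition; alternatives (e.g. normalizing by the maximum
  per-segment detection) would shift activity values but not the
  detection machinery.
* The Horn–Schunck variant is the textbook scheme, not the proprietary
  modification; absolute index values (hence the calibrated
  `radial_index_min`) are specific to this solver and this simulator's
  signal model.
* Sub-pixel singularity localization is pixel-quantized (0.25 grid units
  at the default grid); adequate against the 1.5-unit clustering radius.
* The exponential-dwell ON/OFF model makes 60-s realized ON fractions
  scatter by roughly ±10 percentage points around their target, which
  bounds how tightly any prevalence-vs-target comparison can be read.
* With always-ON sources and short (≈12 s) recordings, junk tracks can
  occasionally exceed the 20 % dominance bar because prevalence is
  quantized to few segments; cohort-level analyses therefore use the
  leading track per recording.

## A worked example

```{r example, eval = FALSE}
library(egflow)

sp  <- source_spec("D4", "focal", cycle_length_ms = 170,
                   dwell_on_s = 6, dwell_off_s = 6,
                   capture_radius = 12, entrain_jitter_ms = 3)
sim <- simulate_recording(specs = list(sp), duration_s = 60,
                          background = list(cl_mean_ms = 185,
                                            cl_spatial_sd_ms = 18),
                          rng_seed = 11)
m   <- egf_map(sim$recording)
m$tracks[[1]]                      # leading source track
ent <- egf_entrainment(m)
ent$entrainment$pct_sd_reduction   # spatial CL SD reduction when ON
```
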