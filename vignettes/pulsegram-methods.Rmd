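---
title: "Methods: vital-sign extraction and calibration-free blood pressure from wearable ECG/PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vital-sign extraction and calibration-free blood pressure from wearable ECG/PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pulsegram implements the analysis core of a sternal wearable
cardiovascular monitor: deriving the standard vitals panel (heart rate,
SDNN heart-rate variability, ECG-derived respiration, pulse-oximetry
SpO~2~, SNR, signal-quality gating) from ECG/PPG sessions, and a
calibration-free blood-pressure predictor that converts 10-s
photoplethysmogram segments into Morlet-wavelet scalogram images and
regresses systolic/diastolic pressure with a residual convolutional
network. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish.

## Vital-sign derivations

**R-peak detection.** The detector is an energy detector in the
Pan–Tompkins tradition: a zero-phase 5–25 Hz bandpass isolates QRS
energy, which is differentiated, squared, and integrated over a 150-ms
window; candidates above an adaptive threshold (a fraction, default
0.35, of the 99.5th percentile of the integrated energy) are refined to
the raw-ECG extremum within ±60 ms, with a 200-ms refractory period.
The refinement step matters: downstream respiration estimation reads the
*amplitudes* at the returned indices, so the indices must land on the R
wave itself, not on the energy centroid.

**Heart rate and SDNN.** Heart rate is `60 / mean(RR)`; HRV is reported
as SDNN, the sample standard deviation (n−1) of successive inter-beat
intervals in milliseconds. No ectopic-beat rejection is applied — with
short windows a single mis-detection inflates SDNN, which is why
session summaries pair it with the quality gate. Whether a deployed
system should reject ectopics is a clinical-configuration question we
deliberately leave to the caller.

**ECG-derived respiration.** Respiration modulates R-peak amplitudes;
the amplitude series is spline-interpolated to a uniform 4-Hz grid,
linearly detrended, and the dominant FFT peak in 0.1–0.7 Hz
(6–42 breaths/min) is reported with parabolic peak interpolation. Two
failure modes return an explicit missing value with a reason: a flat
amplitude series (no modulation to detect, relative SD below 10⁻⁴), and
no spectral peak at least 5× the mean in-band power. The 5× ratio was
chosen once, on the synthetic corpus, as the point separating clean
modulation from white-noise spectra; it is a configuration argument.

**SpO₂.** Ratio-of-ratios oximetry: per window,
`R = (AC_red/DC_red)/(AC_ir/DC_ir)` with DC the window mean and AC the
RMS of the 0.8–8 Hz band. Band-limited RMS replaces peak-to-peak because
it is far more robust to noise while being proportional to it for a
fixed pulse shape — and any fixed proportionality constant cancels in
the ratio. The calibration line `SpO2 = 110 − 25R` (clipped to
[70, 100]) is the widely used empirical line for this sensor class; the
hardware vendor publishes no device calibration, so the line is a
configuration default that a production deployment should replace with
a bench calibration.

**Quality gating.** Three standard signal-quality indices gate each
window: sample skewness, perfusion index (PPG only, AC as a percentage
of DC, minimum 0.2%), and mean beat-template correlation (minimum 0.7).
Skewness bounds are per kind — ±3 for PPG but ±12 for ECG, because the
sparse positive QRS spikes of a *healthy* ECG make it strongly
right-skewed, and a symmetric-looking ECG window is the suspicious one.
The gate fails when any index is out of bounds and names the first
failing index, mirroring the prompt-the-user behaviour of a deployed
monitor. The bounds were fixed once against the synthetic corpus
(clean generated signals pass; white noise and constant signals fail)
and live in one configuration list.

## Blood-pressure pipeline

**Preprocessing.** PPG is bandpass filtered 0.8–8 Hz with a
fourth-order Butterworth. Filtering is applied forward–backward (zero
phase): the filter's group delay would otherwise shift pulse landmarks
relative to the paired arterial-pressure channel, and label/input
alignment matters more here than causal filtering. Records are cut into
non-overlapping 10-s segments; a trailing partial segment is dropped.
Per record, segments whose sample SD falls outside the interquartile
range (inclusive bounds, linear-interpolation "type 7" quartiles) are
discarded at both extremes — motion artefacts and dropouts manifest as
variance outliers. Arterial-pressure peaks (systolic) and troughs
(diastolic, via the negated signal) are found with a 300-ms minimum
spacing (supports ≤200 bpm) and a 10-mmHg default prominence to skip
dicrotic ripple. A segment is labelled with the mean systolic and mean
diastolic amplitude only if *every* systolic peak lies in [80, 180] and
every trough in [50, 100] mmHg; a single excursion rejects the whole
segment rather than the offending beat, the conservative reading of a
plausibility screen. Rejection counts are tallied so that
`accepted = total − IQR-rejected − label-rejected` holds exactly; the
suite asserts this identity.

**Scalograms.** Each retained segment is resampled to the transform
rate with windowed-sinc (Kaiser-windowed, anti-aliased) interpolation
and transformed with a complex Morlet wavelet,
ψ(t) = exp(iωt)·exp(−αt²), over 120 linearly spaced scales on the
half-open interval [20, 140) in samples. At the default 120 Hz
transform rate a 10-s segment gives exactly 1200 columns, hence
120 × 1200 images; the magnitude image is z-scored by its own mean and
SD. Numerical choices:

* ω = 6, α = ½ — the conventional analytic Morlet (≈6 cycles under the
  envelope). An envelope as narrow as one cycle would make the scale
  axis nearly uninformative for ridge localisation, so α is kept at the
  field-standard ½.
* A 1/s pseudo-frequency grid over a 7-fold scale span cannot cover the
  10-fold 0.8–8 Hz band exactly: with ω = 6 the low edge lands at
  0.82 Hz (within 2%) while the high edge reaches 5.7 Hz. The band
  coverage is therefore approximate by construction, which the tests
  encode explicitly (low edge within 5%, high edge within 30%).
* The transform is computed by FFT cross-correlation with zero padding,
  wavelets truncated at ±4 envelope SDs; a direct summation oracle in
  the test suite bounds the truncation error below 10⁻³ relative.
* The segment mean is removed before the transform. Bandpassed PPG is
  already zero-mean; removing the mean keeps the zero-padded transform
  free of offset-driven edge artefacts and makes the z-scored image
  exactly invariant to affine changes of the input — the property the
  suite asserts.
* Row 1 is the smallest scale (highest pseudo-frequency); the scale and
  pseudo-frequency axes are stored in the image object.
* A `reduced` preset (60 scales 10–70 at 60 Hz → 60 × 600 images)
  covers the same frequency band at a quarter of the compute and is
  used for the desk-scale experiment below.

**Network.** The regressor is a residual CNN: a 7×7 stride-2 32-channel
stem (batch norm + ReLU), then three residual blocks with 64, 128 and
256-channel outputs. Each block downsamples by two via a strided 3×3
convolution followed by a second 3×3 convolution (both batch
normalised), with a 1×1 strided projection on the shortcut and the ReLU
after the addition; global average pooling feeds a 256→64→2 head. With
"same" padding every stage maps spatial size n to ⌈n/2⌉, so a default
input undergoes four halvings — the suite checks the per-layer shape
arithmetic and the residual contract (a block with zeroed main path
equals its normalised shortcut projection). The stem width, block
interior depth and head widths are our own choices where the
architecture family leaves them open; they are parameters of
`network_spec()`, not constants.

The loss is the batch mean of half the squared error summed over the
two outputs plus an explicit L2 penalty, λ/2·‖w‖², on convolution and
dense weights only — biases and batch-norm parameters are excluded, and
the penalty enters the loss (coupled weight decay) rather than as
decoupled decay, matching the ridge-regression form of the recipe.
Training uses Adam with learning rate 0.001, first-moment decay 0.9
(the natural reading of "momentum 0.9" for Adam, which has no classical
momentum term; β₂ keeps its 0.999 default), batch size 32, and a
20-epoch cap with validation-based early stopping (patience 5); the
parameters reported are those of the best validation epoch. Runs are
bit-reproducible given the seed: initialisation, the train/validation
split and the per-epoch shuffles all derive from it, and the
single-threaded numerical path is deterministic.

Labels are standardised during training by default (centre/scale from
the training labels, predictions mapped back to mmHg). At desk scale —
a few hundred images and at most 200 optimiser steps inside the
20-epoch budget — raw-mmHg targets sit ~100 standard deviations from a
small-weight initialisation and cannot be reached; standardisation
removes that obstacle without touching the optimiser recipe. The
output layer is initialised near zero so predictions start at the
(standardised) label mean. Training in raw mmHg remains available via
`standardize_labels = FALSE`.

The engine itself (batched im2col+GEMM convolutions in single
precision, batch normalisation, Adam) is implemented in C++ within the
package; evaluation-mode prediction uses running normalisation
statistics and is therefore independent of how inputs are batched,
which the suite checks to 10⁻⁵.

**Evaluation.** Per output the report gives the mean absolute error and
the SD of the absolute errors on a provenance-checked held-out set
(overlap with training segments raises an error), plus pass flags for
the clinic-grade criterion (MAE ≤ 5 mmHg and error SD ≤ 8 mmHg).

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their parameters and seed
(bit-identical on repetition) and each returns its own ground truth.

* `synth_ecg()`: Gaussian-template QRS trains with respiratory amplitude
  modulation `1 + depth·sin(2πf_resp t)`, optional Gaussian beat-interval
  jitter with known SD, and white noise.
* `synth_dual_ppg()`: red/infrared channels sharing one pulse waveform
  with DC offsets and AC amplitudes arranged so the ratio-of-ratios
  equals the requested value exactly in the noiseless case.
* `synth_coupled_ppg_abp()`: 10-s paired segments whose latent
  (SBP, DBP) is drawn from truncated normals (inverse-CDF sampling;
  SBP on [80, 180], DBP on [50, 100] with SBP − DBP ≥ 20 enforced by
  truncating the diastolic draw). The arterial pulse is a half-cosine
  upstroke with a two-Gaussian decay carrying a dicrotic shoulder,
  scaled so peak and trough equal SBP and DBP exactly. The PPG encodes
  the labels through a fixed `linear_morphology` mapping: pulse
  amplitude `0.01·(SBP − DBP)` a.u., systolic rise-time fraction
  `0.35 − 0.0015·SBP` (so 80→0.23 and 180→0.08 of the cycle — a
  physiologically signed, clearly visible shape change). The mapping is
  closed-form invertible from noiseless PPG (`invert_ppg_morphology()`),
  which is the sanity oracle that the learning task is well-posed.
  Default PPG noise is 2% of the mean pulse amplitude as a *fixed
  absolute* SD.

These waveforms emulate the geometry of the real problem — morphology
that varies smoothly with pressure, labels bounded by a plausibility
window, variance-based segment rejection — but not motion artefacts,
baseline wander, sensor coupling changes, beat-to-beat morphology
variability, or the physiological diversity of real patients.
Consequently the synthetic experiment validates the *pipeline* (that
filtering, segmentation, labelling, the transform, the network and the
training loop are wired correctly and can extract a morphology-encoded
pressure signal at clinic-grade error), not the clinical accuracy of
any real-data model: headline accuracies on archival waveform databases
are reproducible only with that external data, which this package does
not ship.

One consequence of z-scoring scalograms individually is worth stating:
per-image normalisation erases absolute pulse amplitude, so under the
morphology mapping the *direct* carrier of diastolic information
(amplitude) is normalised away, while systolic pressure (carried by
rise time, a shape feature) survives unharmed. Because the generator
adds noise at a fixed absolute SD, the post-normalisation noise floor
still encodes relative amplitude, so some diastolic signal remains
learnable indirectly — in practice the experiment recovers systolic
pressure much more accurately than diastolic. The desk-scale criterion
is therefore gated on systolic recovery; diastolic error is reported
alongside it.

## The desk-scale experiment

`run_bp_experiment()` generates 800 coupled segments
(SBP ~ N(120, 15²) truncated to [80, 180], DBP ~ N(75, 8²) truncated to
[50, 100], heart rate 75 bpm, 2% amplitude noise), runs the full
preprocessing chain (the IQR filter retains ~50%, leaving ≈400 labelled
segments), renders reduced 60 × 600 scalograms, holds out 20% of the
segments, and trains with the recipe above (by-segment split — the
synthetic corpus is a single record, so a by-subject split is undefined
here; both policies exist for real data). The held-out systolic MAE and
error SD are compared against the 5 ± 8 mmHg device criterion. The run
takes roughly ten minutes on one CPU core; `scripts/acceptance.R`
re-runs it from scratch and writes the result as JSON. Problem sizes
(800 segments, reduced images) were chosen as the smallest experiment
that exercises every stage while leaving the learning task comfortably
solvable.

## Group statistics

The statistics module mirrors the comparisons used in remote-monitoring
studies: Welch's unequal-variance t-test (Welch–Satterthwaite degrees of
freedom, never rounded; two-sided p-values), Levene's test (classic
mean-centred by default since that is the test named in the
literature; the Brown–Forsythe median variant is an option), and
Games–Howell pairwise testing — Welch statistics referred to the
studentized-range distribution with q = |t|·√2 — with a compact letter
display. The letter display grows one mutually-compatible set around
every non-significant pair and absorbs subsets, guaranteeing that
groups share a letter exactly when they are not significantly
different (minimality of the letter count is not guaranteed, and not
needed). With two groups Games–Howell reduces to Welch's t exactly,
which the suite checks to 10⁻⁶; Welch's type-I error is calibrated
against 2000 null simulations. Degenerate inputs follow explicit
conventions: zero variance in both groups with equal means gives
t = 0, p = 1 with a flag. The studentized-range CDF is base R's
`ptukey`; group comparisons of session vitals aggregate to per-subject
means first to avoid pseudo-replication of windows.

## Known limitations

* The WFDB reader covers the header + format-16 signal subset
  (gain/baseline scaling, invalid-sample sentinel → `NA`); annotations,
  multi-segment records and other storage formats are out of scope.
* SpO₂ uses a generic calibration line, not a device calibration.
* SDNN applies no ectopic/artefact rejection.
* The synthetic generators use white noise only; conclusions about
  robustness to structured artefacts cannot be drawn from them.
* Clock alignment models a single fixed offset per session, not drift.
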