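---
title: "Methods: emotion and arousal classification from wearable ECG and EDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion and arousal classification from wearable ECG and EDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Problem and pipeline

`emophysio` analyzes wearable recordings from an emotion-induction
protocol: a subject watches seven 30 s image stimuli (anger, disgust,
fear, happiness, neutral, sadness, surprise), each followed by 60 s of
rest, a 30 s autobiographical recall and another 60 s of rest, preceded
by a 30 s baseline — 29 intervals in total. Electrodermal activity
(skin-conductance level, SCL, 32 Hz) and ECG (1024 Hz) are recorded;
after each stimulus the subject self-reports arousal on the 9-point SAM
scale.

The analysis runs in two branches:

1. **EDA branch** — clean the SCL trace and detect the stimulus *trigger
   marks*, which define the ECG segmentation.
2. **ECG branch** — down-sample to 256 Hz, segment on the triggers,
   remove raw-signal outliers, extract R peaks and RR intervals, clean
   the RR series, and compute eight heart-rate-variability (HRV)
   features per segment. A Gaussian-kernel SVM classifies each segment
   as *emotion* vs *rest*; emotion segments are converted to Morlet CWT
   scalogram images and a small CNN classifies arousal strength
   (low/mid/high, from SAM 1–3 / 4–6 / 7–9).

The recordings that motivated this design are not publicly available,
so the package ships a synthetic-session generator that emulates the
protocol and the relevant signal properties; every stage is tested
against that generator's ground truth.

## The synthetic world

`generate_cohort()` draws, per subject, a resting heart rate
$\mathrm{HR}_0 \sim \mathcal N(70, 5^2)$ bpm and a beat-to-beat RR
standard deviation $\sigma_{RR} \sim \mathcal U(30, 50)$ ms — typical
adult resting values. Emotion stages (stimulus and recall) elevate HR
by `emotion_hr_shift` (default 10 bpm) and scale $\sigma_{RR}$ by
`emotion_rmssd_scale` (default 0.7): sympathetic activation raises
heart rate and suppresses RMSSD. ECG is a sum-of-Gaussians PQRST
template placed at cumulative RR times; the RR sequence carries
sinusoidal modulation at 0.1 Hz (LF) and 0.25 Hz (HF) plus white
jitter, with half the variance sinusoidal and half white. SCL is a
tonic level in the physiological 2–20 µS range with slow drift, plus a
bi-exponential phasic response ($\tau_\text{rise} = 0.75$ s,
$\tau_\text{decay} = 2$ s, standard skin-conductance-response
morphology) of amplitude `scr_amplitude` (default 0.5 µS) at every
stage onset.

Artifacts are injected at Poisson rates (default 0.2/min each): NaN
runs of 0.5–3 s (exercises spline gap filling), sub-zero dips
(exercises the zero floor) and ECG spike bursts of ≥ 5× the R amplitude
and < 0.5 s (exercises the sliding-window outlier removal). The study
the protocol mirrors gives no artifact statistics; these rates are free
parameters chosen to make each cleaning stage do real work in tests.

Each emotion segment receives a SAM label drawn from the empirical
9-point distribution (24, 26, 34, 29, 51, 41, 31, 19, 11 over ratings
1–9). The label modulates the R-wave amplitude sinusoidally at 2 Hz
with depth `arousal_effect(sam)`, default linear from 0.05 to 0.35.
The cap at 0.35 is deliberate: beat-amplitude modulation much beyond
~35% is not physiological (respiratory amplitude modulation is weaker
than that) and would make beats undetectable by construction, which we
confirmed while validating per-stage RR recovery. Ground truth stored
per session includes the trigger times, the *realized* per-stage mean
RR (computed from the placed beats — comparing the pipeline against
the configured parameter would confound detector error with the
sampling noise of ~35 beats per segment), and the SAM labels.

**What a green test does not establish.** The generator produces one
beat morphology, stationary stage-wise statistics, additive artifacts
and an arousal signature that is visible by construction. Real
recordings have inter-subject morphology differences, movement
artifacts, respiration coupling and — critically — no guarantee that
arousal is expressed in the ECG at all. Classifier accuracies on
synthetic cohorts validate the implementation, not the physiology.

## EDA branch

`fill_gaps()` interpolates NaN runs with a cubic spline fitted on the
non-missing samples; leading/trailing runs are filled by nearest-value
extension (spline extrapolation is unstable) with a warning.
`floor_negative()` clips negative values to zero — skin conductance is
non-negative by physics.

`detect_triggers()` looks for stimulus onsets as positive peaks of the
second-order finite difference: a phasic response begins with an abrupt
slope increase, so the onset is a deflection point. The signal is
moving-average smoothed (`smoothing_s`, default 1 s), differentiated
twice, smoothed again, and peaks are picked with a minimum separation
(default 15 s, half the shortest stage) and a relative prominence
threshold (default 0.1 of the maximum magnitude). Two numerical
choices matter:

* **Artifact masking.** Exact zeros only arise from the flooring step,
  so samples within 2 s of a zero-valued run are removed from both the
  prominence reference and the peak candidates. Without this, a single
  floored dip dominates the derivative by orders of magnitude and
  suppresses every genuine trigger.
* The prominence reference is the post-masking maximum; on
  artifact-free signals the masking is a no-op.

`triggers_to_segments()` turns consecutive triggers into half-open
intervals labeled by protocol position; the final interval closes at
the session end. `trigger_rmse()` pairs predicted and true marks
greedily by smallest time difference and reports
$\sqrt{\tfrac1N\sum_i (x_i - \hat x_i)^2}$ over matched pairs, with
unmatched marks counted as misses/false alarms.

## ECG branch

`downsample()` uses a 65-tap zero-phase windowed-sinc FIR (cutoff 80%
of the new Nyquist) before decimation. A zero-phase FIR was chosen
over an IIR decimator because phase distortion would shift R-peak
times, which are the measurement.

`remove_raw_outliers()` tiles each snippet into 1 s windows, computes
each window's min and max, and tags windows whose min is more negative
than 2.5× the mean window minimum or whose max exceeds 2.5× the mean
window maximum (window minima are negative, so "less than 2.5× the
mean min" means *more negative*). A tagged window is replaced by its
nearest untagged predecessor, or its nearest untagged successor when no
untagged predecessor exists (first window, or a tagged run at the
start). Thresholds are computed per snippet. Output length never
changes and untagged windows are returned bit-identically.

`detect_r_peaks()` is a Pan–Tompkins-style detector (5–15 Hz band-pass,
five-point derivative, squaring, 150 ms moving integration, adaptive
threshold at 0.25× the upper-tail integrated energy, 200 ms refractory
constraint), with each detection refined to the band-passed local
maximum within ±100 ms for sample accuracy.

`clean_rr()` applies the two-sided generalized extreme Studentized
deviate test to the interval sequence (α = 0.05, at most 10% of
intervals — the common defaults of the reference implementation
family), then replaces flagged intervals by modified Akima cubic
Hermite interpolation *over the interval index*, because the series is
cleaned after discarding values, not resampled in time. Peak times are
rebuilt from the first peak plus cleaned cumulative intervals so the
series invariants hold. A session is dropped when more than 20% of its
segments are unusable (fewer than two detectable beats, or every
window tagged), mirroring quality-control subject removal.

## HRV features

Per segment (30 s emotion/baseline, 60 s rest — the windows are the
segments themselves):

* RMSSD $= \sqrt{\tfrac{1}{N-1}\sum (RR_{i+1}-RR_i)^2}$;
* SDNN with **1/N** (population) normalization, exactly as the defining
  formula prints it, not the sample 1/(N−1) convention;
* mean RR and HR $= 60000/\mu$;
* Lomb–Scargle periodogram of the inherently unevenly sampled
  (peak time, interval) series on a 512-point log-spaced grid over
  0.003–0.4 Hz, classic (unnormalized) form, power in ms²;
* band powers as sums of periodogram values **strictly** inside
  HF 0.15–0.4, LF 0.04–0.15, VLF 0.003–0.04 Hz (a point exactly on a
  boundary belongs to neither band), summing $P$ — not $P^2$ — as the
  defining formula states despite its "sum square energy" phrasing;
* HF/LF ratio, reported missing when LF = 0 and imputed with the
  training-column median at normalization.

Normalization is min–max per feature column, fit on the training
partition only and applied with clipping to the other partitions. The
alternative reading (per-observation rows) would destroy inter-feature
magnitude information across only 8 features, so the per-column axis
was chosen and is documented here as an open interpretation.

## Scalograms

`cwt_scalogram()` computes the analytic Morlet CWT at integer scales
1–512 (frequency-domain implementation, zero padding, cone-of-influence
half-widths in the metadata). The configured time-bandwidth value
0.234 is carried in the metadata, but the implemented wavelet is the
standard analytic Morlet with center frequency ω₀ = 6 and unit-variance
envelope: a plain Morlet's time-bandwidth product is fixed at 1/(2π),
so the requested value cannot be realized without changing wavelet
family; the mapping is fixed and documented rather than silently
approximated. Scale a maps to frequency $f = \omega_0 f_s / (2\pi a)$.

`scalogram_to_image()` divides by the maximum (making rendering
invariant to input scaling), log-compresses, min–max scales to [0, 1],
bilinearly resizes, and replicates to three channels — a reproducible,
colormap-free rendering.

## Classifiers

**State SVM.** Gaussian kernel with the convention
$K(x,y) = \exp(-\lVert x-y\rVert^2 / s^2)$ — the convention under which
the printed hyperparameters (scale 6.385, box constraint 956.32) are
meaningful. The dual problem is solved by SMO with deterministic pair
selection (so identical data and seed give identical models). No SVM
library exists in the supported environment, which is also why the
solver is part of the package. Probabilities come from Platt scaling
fitted on training decision values (the calibration method is not
specified by the source design; Platt is the standard choice).
Optional Bayesian optimization (Gaussian-process expected improvement,
100 iterations, inner 5-fold CV) searches kernel scale and box
constraint log-uniformly in $[10^{-3}, 10^3]^2$; the search ranges are
a documented choice. "One-vs-one" coding is vacuous for two classes
and kept only in the configuration for fidelity.

**Arousal CNN.** The default backbone is a small 4-conv-block network
(8/16/32/32 filters, 3×3 kernels, max-pooling after the first three
blocks, fully connected head), trained with SGD + momentum 0.9,
learning rate 0.001, mini-batch 30, 12 epochs, shuffling every epoch,
per-array L2 gradient clipping at 1.0, and the class-weighted
cross-entropy loss
$-\tfrac1N \sum_n \sum_i w_i T_{ni} \ln Y_{ni}$ with $w_i = N/m_i$
(zero probabilities clamped at $10^{-12}$). Convolutions are im2col
matrix products with exact backpropagation, verified against numeric
differentiation in the test suite. A ResNet-50 backbone would require
pretrained weights that cannot be distributed offline; requesting it
raises an informative error.

## Evaluation

Monte Carlo cross-validation is repeated stratified random
sub-sampling: k = 5 independent 80/20 splits (the scheme names the
fold count but not the validation fraction; 1/k is the exposed
default). The two-class dataset pools the 7 emotion categories against
their rest periods and excludes the baseline segment (the bookkeeping
tables list only categories and rest; 266 + 266 accounts for all
non-baseline segments of 19 subjects). TP accuracy is the confusion
diagonal over the total; per-class precision/recall/F1 are macro
averaged, with undefined precisions (empty predicted class) excluded
from macro means and counted. The 90/10 arousal split enforces that
every 9-point SAM value present in the data appears in the test set.

## Known limitations

* The CSV session dialect is the only on-disk format (no HDF5 binding
  is available in the supported environment).
* The arousal CNN on synthetic cohorts learns the planted modulation;
  no claim transfers to real recordings.
* Appendix-level tie-break details of the window-replacement rule for
  *interior* runs of tagged windows (predecessor-preferred) are a
  documented choice.
* The Lomb–Scargle grid, normalization and absence of detrending are
  fixed documented choices; the source design leaves them open.
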