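---
title: "Cuff-less blood pressure estimation from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuff-less blood pressure estimation from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arterial blood pressure (BP) is usually measured intermittently with a cuff,
which misses its continuous dynamics and is impractical for wearables. The
photoplethysmogram (PPG) — the optical blood-volume signal behind every
smartwatch heart-rate sensor — carries morphological information that
correlates with BP: vascular stiffness and peripheral resistance reshape the
systolic upstroke and the dicrotic wave. `ppgbp` implements an end-to-end
pipeline that regresses systolic (SBP) and diastolic (DBP) pressure, in
mmHg, from 3-second PPG windows using a one-dimensional residual network
with a multi-scale stem and squeeze-and-excitation (SE) channel attention,
trained with the Huber loss, and evaluated against the AAMI and BHS device
standards.

Everything runs on synthetic paired PPG/ABP waveforms from the package's
own simulator, so the full pipeline is testable without any data download
or physiological recordings.

## The synthetic waveform simulator

Each cardiac cycle is a sum of Gaussian lobes on the beat's local time
axis: an asymmetric systolic lobe (rise width 0.6 s1, fall width 1.4 s1 —
the fast upstroke / slow runoff asymmetry of real PPG, which also gives
clean beats the positive skewness that the quality screen presumes) and a
dicrotic lobe scaled by `dicrotic_strength`. BP is *deterministically
coupled to morphology*, not to amplitude:

* systolic lobe width `s1 = 0.09 - 0.035 (SBP - 90)/90` s — sharper peaks
  at higher SBP;
* dicrotic delay `d = 0.16 + 0.10 (DBP - 50)/40` s and dicrotic width
  `s2 = 0.045 + 0.02 (DBP - 50)/40` s — later, broader dicrotic waves at
  higher DBP.

Coupling through shape is essential: the pipeline min–max normalizes every
window, so amplitude-coded BP would be erased and no learner could recover
it. The couplings are monotone, making BP identifiable from morphology in
principle; the network's job is to read pulse geometry.

The ABP channel is the same per-beat pulse train affinely mapped so each
beat's maximum equals the target SBP and its minimum the target DBP
(noise-free, so reference extraction can be validated to 0.1 mmHg). The
PPG channel adds baseline drift (default 0.1 Hz, amplitude 0.2 of the unit
pulse), powerline interference (50 Hz, amplitude 0.05 — deliberately above
the 8 Hz pass-band so filtering has a measurable stop-band target) and
white noise (sd 0.05). Beat periods get ±3% uniform jitter, rescaled to
tile the record exactly; this keeps the autocorrelation quality index
strictly below 1 so the screen is actually exercised. Per-beat ground
truth (onsets, SBP, DBP) is stored in `meta` because real intensive-care
datasets provide reference pressures without documenting their extraction;
the simulator exposes them directly for oracle use.

What the simulator does *not* emulate: pulse-transit-time effects, motion
artifacts, arrhythmias, pathological waveforms (e.g. absent dicrotic
wave), sensor saturation, and inter-subject variability beyond the BP/HR
couplings. Passing tests on synthetic data therefore demonstrate that the
implementation is correct and that the architecture can learn
morphology-coded BP — not that it reaches any particular accuracy on
clinical recordings.

## Conditioning and quality screening

Stage order is fixed: filter → segment → screen → normalize.

1. **Filtering.** A 4th-order Butterworth band-pass, 0.5–8 Hz, removes
   baseline drift and high-frequency interference. The filter is designed
   analytically and applied as cascaded biquads whose numerator zeros sit
   exactly at z = ±1: at these narrow normalized cut-offs (0.5 Hz at
   125 Hz sampling) a single order-8 transfer function visibly leaks DC
   through coefficient rounding, while the cascade annihilates constants
   to machine precision. Zero-phase (forward–backward) application is the
   default because phase distortion would bias the derivative channels;
   causal mode is available. Zero-phase doubles stop-band attenuation in
   dB, so tests use the single-pass analytic response as a lower bound.
2. **Segmentation.** Non-overlapping 3-s windows (375 samples at 125 Hz);
   the stride is configurable for overlapped variants. ABP is cut at
   identical offsets but never filtered or normalized — labels must stay
   in mmHg.
3. **Reference extraction.** Per-window SBP/DBP are the means of detected
   per-beat ABP maxima/minima (peak picking with minimum separation
   60/180 s and an amplitude gate so the dicrotic bump is not counted),
   falling back to global extrema when fewer than two beats are found.
   This is more robust to a single noisy beat than a global max/min.
4. **Screening.** A window is kept iff SBP ≤ 180 mmHg, DBP ≥ 50 mmHg,
   skewness ≥ 0 and autocorrelation SQI ≥ 0.6. Skewness uses population
   (divide-by-N) moments. The autocorrelation SQI is the maximum
   mean-removed Pearson autocorrelation over lags corresponding to 30–150
   bpm; a quasi-periodic pulse train scores near 1, damaged windows fall
   below the 0.6 threshold. Every rule outcome is recorded per segment so
   exclusion counts reconcile exactly.
5. **Normalization and channels.** The PPG window is min–max normalized
   to [0, 1]; velocity (VPG) and acceleration (APG) channels are first and
   second padded differences, each independently re-normalized. Computing
   derivatives after normalization guarantees the stated [0, 1] input
   range for all three channels.

## MSA-ResNet

The regression network is a 1-D ResNet34-style backbone:

* **Multi-scale stem (MSFE).** Four parallel branches at stride 2:
  regular convolutions with kernels 3, 5 and 7, plus a large-kernel
  (13) branch realized as a depthwise convolution followed by a pointwise
  (kernel-1) channel-mixing convolution. The depthwise-separable split
  costs 3·13 + 3·16 = 87 weights versus 624 for a full kernel-13
  convolution at the same widths, while keeping the wide receptive field.
  Branch outputs (equal length by same-padding) are concatenated along
  channels and reshaped by a kernel-1 convolution.
* **SE residual blocks.** Each block is conv–BN–ReLU–conv–BN, an SE
  module on the residual branch, then the shortcut addition and a final
  ReLU; projection shortcuts (kernel-1, stride-2 conv + BN) where shape
  changes. The SE module squeezes each channel by global average pooling,
  passes the channel vector through a bottleneck MLP (reduction 16, ReLU
  between, sigmoid output) and rescales channels by the resulting gates in
  (0, 1) — channel attention that is also an elementwise contraction.
  Stages follow ResNet34: 3/4/6/3 blocks at 64/128/256/512 channels.
* **Head.** Global average pooling and a fully connected layer with two
  outputs, SBP and DBP jointly, in mmHg.

All operations are one-dimensional (the inputs are 3 × 375 signal
windows); batch normalization and ReLU follow every convolution, which a
34-layer network needs for trainability. SE sits in every block, on the
residual branch before the addition. A `width_multiplier` scales every
channel count so desk-scale variants (×0.25 ≈ 466k parameters vs ≈ 21.5M
at full width) share the full model's code path.

The network, including backpropagation and SGD, is implemented in R on
BLAS matrix operations: feature maps are channels × (length · batch)
matrices, convolutions are im2col gathers plus one matrix product, and
each layer's backward pass is the matching scatter-add. Correctness is
established by numerical-gradient checks and closed-form parameter-count
oracles in the test suite.

## Training

The reference protocol is Huber loss (δ = 1 mmHg), SGD with momentum 0.9,
batch size 1024, 120 epochs, initial learning rate 0.001 with single-cycle
cosine annealing to 0, and a 7:1:2 train/validation/test split. Those are
the package defaults (`train_config()`). Notes:

* With labels in mmHg and δ = 1, Huber behaves like MAE for typical
  residuals (gradients clipped at ±1); it differs from MAE only inside the
  ±1 mmHg knee, where it is smooth.
* The output bias is initialized to the training-set label mean —
  standard regression-head practice; with bounded Huber gradients the
  bias would otherwise crawl from 0 to ~120 mmHg at 1 mmHg per effective
  step.
* Splits default to segment level, mirroring the usual protocol; note
  that segment-level splitting places windows of the same record in
  different partitions, an optimistic setting. `split_unit = "record"`
  gives subject-disjoint splits.
* Momentum 0.9 and weight decay 0 are declared package choices, as is
  best-checkpoint selection by lowest mean validation MAE; the
  per-epoch history records learning rate, training loss and validation
  MAE for both targets.
* Training aborts with a diagnostic on non-finite loss.

### Desk-scale study conditions

The package's built-in study (`run_bp_pipeline()` defaults, also what
`scripts/acceptance.R` reruns) is scaled for a single CPU: 220 records of
30 s (uniform BP sampler: SBP ~ U(90, 180), DBP ~ U(50, 90), pulse
pressure ≥ 20), screened and capped at 2,000 segments; width-×0.25
network; 20 epochs at batch 128 with initial learning rate 0.01. The
learning rate is larger than the full-scale 0.001 because Huber gradients
are bounded at δ = 1: with only ~220 SGD steps, meaningful progress needs
larger steps. These problem sizes keep the whole study at a few minutes of
CPU time while leaving the learning signal intact: the trained network
reaches a held-out MAE several times better than a constant-mean
predictor, passing the morphology-recovery bar (SBP ≤ 8, DBP ≤ 5 mmHg)
with margin.

Validation MAE is noisy mid-training: with ~15 steps per epoch the
batch-norm running statistics lag behind fast-moving weights at high
learning rate, so inference-mode metrics can spike before the cosine decay
settles them. Best-checkpoint selection makes this benign.

For the loss-robustness ablation (5% gross label outliers of ±60 mmHg),
Huber and MSE are each trained at a stable learning rate of their own:
MSE gradients scale with the residual (tens of mmHg), so at Huber's rate
MSE is far outside its stable region and the comparison would be vacuous.
MSE uses the best rate from a small grid calibrated once in its favor
(0.003); Huber keeps the study default (0.01). Both arms train to
convergence (20 epochs), and validation MAE is measured against the clean
ground-truth labels — the simulator has them, and the shared outlier floor
of corrupted-label validation would otherwise dilute the contrast. The
comparison is directional — Huber's validation MAE must not exceed MSE's —
and no exact margins are claimed.

## Evaluation

Errors are `reference − predicted` throughout. Reports contain, per
target:

* **ME / SD / MAE** — SD is the sample standard deviation of errors about
  their mean (the standard device-evaluation usage). The uncentered
  variant `sqrt(sum(e^2)/(n−1))` is available as `sd_as_printed = TRUE`
  for comparison with reports that print that form.
* **AAMI verdict** — pass iff |ME| ≤ 5 mmHg and SD ≤ 8 mmHg; bounds are
  treated as inclusive (boundary behavior is unobservable in practice and
  must simply be declared).
* **BHS grade** — cumulative percentages of absolute errors within
  5/10/15 mmHg; grade A requires 60/85/95, B 50/75/90, C 40/65/85, and
  anything below C is graded D (the protocol's below-C verdict).
* **Bland–Altman** — mean difference and 95% limits of agreement
  (mean ± 1.96 SD), plus the percentage of differences inside the limits.
* **Pearson r** between predictions and references (the correlation type
  is assumed Pearson, matching linear regression overlays).

`tidy()`, `glance()`, `autoplot()`, `plot_bland_altman()` and
`plot_regression()` expose reports as tibbles and ggplots; JSON reports
round-trip at full double precision.

## Numerical choices and degenerate inputs

* Filter: biquad cascade (see above); reflection padding of 10/`low_hz`
  seconds absorbs the slow low-edge transient in zero-phase mode.
* Constant (zero-variance) windows: skewness and the autocorrelation SQI
  return `NA`, which auto-fails screening as "degenerate"; min–max
  normalization of a constant raises an error, as does a constant
  derivative channel (e.g. a linear ramp's VPG).
* Flat ABP windows (range < 1 mmHg) yield `NA` references — a recorded
  quality failure, not an exception.
* Max-pool ties break toward the earliest window position; padding
  positions never win (−Inf fill).
* Batch norm uses ε = 1e−5 and running-statistic momentum 0.1; batches of
  size 1 are skipped during training (batch statistics undefined).
* Seeds: one user seed fans out to stage streams via a deterministic
  string hash (`derive_seed`), all below 2^31; identical configurations
  are bit-reproducible for a fixed BLAS.

## Known limitations

* Synthetic-only validation; see the simulator section for what is not
  emulated. Accuracy numbers on the synthetic study say nothing
  quantitative about clinical data.
* Segment-level splitting (the default, matching common practice) leaks
  records across partitions; record-level splitting is one flag away and
  is the honest setting for subject generalization claims.
* The record/dataset readers handle the package's own CSV container
  format; binary waveform containers are out of scope.
* Full-scale training (batch 1024, 120 epochs, tens of thousands of
  segments) is supported by the same code path but is not practical on a
  single CPU; the defaults encode the protocol, not the expectation that
  you run it on a laptop core.
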