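---
title: "Estimating arterial blood-pressure waveforms from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating arterial blood-pressure waveforms from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem

Arterial blood pressure (ABP) is measured continuously only by invasive
catheterization; photoplethysmography (PPG) is a cheap optical signal
available on wearables. Because blood-volume changes in the microvasculature
are driven by the same cardiac cycle that shapes the pressure wave, a PPG
record carries substantial information about the concurrent ABP waveform.
`ppgbp` treats cuff-less blood-pressure estimation as sequence regression:
learn a mapping `f` from a PPG window `X` to the synchronized ABP window
`Y = f(X)` (both 1024 samples at 125 Hz, about 8 s), and read the clinical
parameters off the predicted waveform:

* SBP (systolic) = max of the predicted window,
* DBP (diastolic) = min of the predicted window,
* MBP (mean) = (SBP + 2 DBP) / 3.

## The network

The model is a 1-D encoder-decoder (U-Net style) with three structural
ideas layered on top, each of which can be disabled independently for
ablation (`ablation_grid()` enumerates the seven combinations):

**Sparse residual blocks.** Encoder blocks place an additive skip after
*every* conv + batch-norm stage: `y1 = BN(conv(x)) + x`,
`y2 = BN(conv(y1)) + y1`, `out = ReLU(y2)`; decoder blocks use the
single-stage form. This is denser shortcutting than the ordinary residual
unit `ReLU(F(x) + x)` (also provided), and a 1x1 convolution aligns
channels on the skip path when they differ. Where the block is described
in prose as "concatenating" the original information, the formal residual
definition is additive, and addition is what is implemented.

**SE-GRU attention on skips.** Each skip connection is recalibrated per
channel before concatenation. Channel descriptors come from global average
pooling (`squeeze_channels()`). The classic squeeze-and-excitation module
learns the excitation with a bottlenecked pair of fully connected layers;
the recurrent variant instead scans the length-C descriptor sequence with a
GRU (hidden size C/r, reduction r = 8 by default), projects each hidden
state to a scalar, and passes it through a sigmoid
(`se_gru_weights()`). The GRU follows the standard gate equations exactly
(`gru_step()`), with the update gate weighing the candidate state — this is
asserted against a literal transcription in the tests, so a framework-style
variant cannot slip in silently. How the descriptors enter the GRU is not
fully pinned down by the source description; scanning channels as a
sequence of scalar inputs is this package's reading, chosen because it
models cross-channel dependencies with the fewest extra assumptions and
makes the weights order-sensitive (which the fully connected excitation is
not).

**Deep supervision.** Besides the full-resolution `out` head, each of the
four decoder levels gets a 1x1-conv auxiliary head, linearly upsampled to
the input length. The loss is the weighted sum of per-head mean absolute
errors against the same target waveform, with weights
`[1, 0.9, 0.8, 0.7, 0.6]` for `[out, level1..level4]`. The attachment
order (whether `level1` is the shallowest or deepest decoder output) is
not derivable from the source; shallow-first is the default and the order
is configurable (`aux_weight_order`). Auxiliary targets are the
ground-truth waveform itself: the formal loss omits the comparand of the
auxiliary terms, and supervising every head with `y` is the standard deep
supervision reading.

Downsampling is 2x max-pooling, upsampling a kernel-2/stride-2 transposed
convolution, kernels are width 3, and channels double per level from
`base_channels`. None of these are fixed by the source description; they
are the conventional U-Net choices and are config-exposed. The engine
itself (convolutions, batch norm, GRU, Adam, backpropagation) is
implemented in R on BLAS matrix operations; every layer's backward pass is
verified against finite differences in the test suite.

## Preprocessing

The record-to-segment chain mirrors the protocol used with the UCI
cuff-less BP corpus:

1. drop records shorter than 8 min (480 s, inclusive boundary — the
   boundary convention is this package's choice);
2. remove PPG baseline drift spectrally: mirror the signal (so aperiodic
   drift does not leak across the spectrum), zero all FFT bins below
   0.5 Hz and taper the gain with a 0.1 Hz raised cosine (the exact
   recipe behind "FFT baseline removal" is unstated; this is the simplest
   spectral high-pass that behaves on finite records);
3. 4th-order Butterworth bandpass 0.5-8 Hz, applied forward-backward for
   zero phase with odd-reflection padding — phase distortion would shift
   systolic/diastolic timing between the input and target;
4. clip outlier peaks beyond mean +- 3 sd (the multiplier is unstated; 3
   is the default and configurable) by linear interpolation from the
   nearest clean neighbours;
5. z-score the PPG per record (population convention);
6. cut non-overlapping 1024-sample windows and split them 6:2:2 into
   train/validation/test by a seeded shuffle with largest-remainder
   apportionment.

Two deliberate deviations from a literal reading:

* **ABP filtering.** The source protocol applies the bandpass to "PPG and
  blood pressure signals", but a 0.5 Hz high-pass would annihilate the DC
  component of ABP — the absolute pressure level that SBP/DBP are read
  from. By default ABP receives only the 8 Hz low-pass branch;
  `abp_mode = "bandpass"` restores the literal behaviour.
* **ABP standardization.** Targets are standardized with the training-set
  global mean/sd, which are stored with every segment so predictions are
  reported in mmHg.

The split is segment-level, matching the sample counts of the reference
protocol; note this allows windows of one subject to appear in both train
and test sets (subject-level leakage), so desk-scale metrics must not be
read as subject-generalization estimates.

## The synthetic generator

`synth_config()` / `synth_dataset()` produce paired PPG/ABP records with
known per-beat ground truth so every stage is testable without the 12,000
record corpus:

* Each record draws a heart rate (55-100 bpm) and an operating point
  (SBP, DBP) uniformly from ranges matching the preprocessed corpus
  statistics (SBP 86-179, DBP 58-134 mmHg), redrawing while DBP is not at
  least 20 mmHg below SBP; an error is raised after 100 attempts for
  infeasible ranges. Note the accept/reject step makes the accepted SBP
  mean sit above the raw range midpoint; tests compare against a
  rejection-sampling oracle, not the midpoint.
* Within a record, SBP and DBP drift slowly (sinusoidal, +-4 mmHg, 0.02 to
  0.08 Hz) with small per-beat noise. Early versions drew every beat
  independently across the full ranges; the resulting step discontinuities
  between beats are unphysiological and the 8 Hz low-pass overshoots them,
  which is why the generator was changed to slow variation.
* Each beat is a two-Gaussian pulse (systolic peak plus delayed, wider
  dicrotic wave) on the DBP baseline, normalized at the sampled maximum so
  the drawn SBP is hit exactly before corruption. The systolic width
  (0.055 s) is wide enough that the prescribed 8 Hz low-pass preserves
  per-beat extrema within 2 mmHg through the full chain.
* PPG is a fixed monotone power warp (`u^2.5` on normalized pressure)
  of the 40 ms-delayed clean ABP, plus sinusoidal baseline drift, sparse
  spike artifacts, and white noise. The warp's curvature matters: PPG is
  z-scored per record downstream, which discards the record mean and
  scale, and under a near-affine warp the absolute pressure level would
  become unidentifiable — the regression task would be ill-posed by
  construction. With an exponent of 2.5 the level leaves a clear
  signature in the pulse asymmetry, so a desk-scale model can learn it.
* One master seed; each record uses an independent substream, so datasets
  are reproducible and records are independent.

What the generator does **not** emulate: real pulse-morphology diversity
(it has one shape family), respiration coupling, reflected-wave physics,
measurement-chain transfer functions, or subject-specific PPG-ABP
relationships. Passing desk-scale tests therefore demonstrates that the
pipeline and optimizer work and that the architecture can fit a
well-posed PPG-to-ABP mapping — not that the model reaches clinical
accuracy on ICU data.

## Training protocol

The reference protocol (`train_config(profile = "paper")`) is Adam,
learning rate 1e-4, batch 256, up to 100 epochs, MAE loss with MSE
monitored, early stopping after 10 epochs without validation improvement.
The desk profile (default) keeps the protocol but uses batch 32 and
learning rate 1e-3 — the reference rate belongs with the reference batch
size; at an 8x smaller batch the step budget per epoch is 8x larger and
the larger rate restores a comparable optimization pace on one CPU.
"Improvement" means a strict decrease of at least 1e-6 (no minimum delta
is stated in the source); the monitored quantity is the full composite
deep-supervision loss on the validation set, since that is the objective
being trained (monitoring the main head alone is possible via the history).
The best-validation parameters are restored after stopping. Histories
record per-head validation MAEs for loss-curve inspection
(`tidy()`, `autoplot()`).

Numerical choices: He-style initialization for convolutions, uniform
(+-1/sqrt(H)) for GRU parameters; batch-norm momentum 0.1, eps 1e-5, eval
mode freezes running statistics (predictions are therefore deterministic
and batch-order independent); max-pool ties break to the left element;
Adam beta = (0.9, 0.999), eps 1e-8.

## Evaluation

`evaluate_bp()` extracts SBP/DBP/MBP per segment from both prediction and
target, then reports per parameter:

* error metrics: ME, MAE, MSE, `std_eq20 = sqrt(MSE)` and the conventional
  dispersion `sd_diff`. The quantity printed as "STD" alongside MAE in
  this literature is algebraically the RMSE, while Bland-Altman and AAMI
  need the dispersion of errors about their own mean; both are computed
  and named distinctly rather than conflated. R-squared and the
  raw-moment Pearson r complete the set.
* BHS grading: percentages of absolute errors within 5/10/15 mmHg
  (inclusive), per-threshold grades A/B/C by inclusive minima
  (60/85/95, 50/75/90, 40/65/85), overall grade the worst of the three,
  "D" when even C fails. Minima are compared at one-decimal precision
  (0.05 percentage-point tolerance): published grade tables in this
  literature treat 94.95% as meeting a 95% minimum while 89.88% does not
  meet 90%, which is exactly comparison after rounding to one decimal.
  `tol = 0` restores the strict rule.
* AAMI check: |ME| <= 5 mmHg, SD <= 8 mmHg, n >= 85 subjects, boundaries
  inclusive (the prose says "less than" but the printed criterion is
  "<= 5 / <= 8"); the subject count is the number of distinct source
  records.
* Bland-Altman: mean difference and mean +- 1.96 sd limits of agreement
  (population sd), with the fraction of points inside the limits.

Waveform-level (sample-by-sample) metrics are pooled across segments.
Reports serialize to JSON/CSV (`write_evaluation()`) and plot as
Bland-Altman, absolute-error histogram, or regression fits (`autoplot()`).

## Problem sizes and degenerate inputs

The bundled tests and the acceptance script run the whole pipeline at desk
scale: ~140 synthetic records of 120 s (about 2,000 segments), a
`base_channels = 8` network (~177k parameters), 8-10 epochs. These sizes
are the package's desk defaults; the architecture scales to the reference
configuration (`base_channels = 32`) unchanged.

Degenerate inputs are handled explicitly: zero-variance signals refuse to
z-score; constant signals pass through peak clipping untouched; an
all-flagged signal is an error; empty containers read as empty record
sets; empty split groups read as empty tables; non-finite training loss
aborts with a diagnostic; prediction refuses mismatched window lengths.

## Known limitations

* MATLAB v7.3 containers (HDF5-based) are not readable; re-save as v5 or
  CSV.
* The dataset store is a Parquet table plus JSON metadata sidecar.
* Training is single-threaded CPU; reproducibility is exact on a given
  BLAS, and practically exact across BLAS builds.
* Segment-level splitting (see above) and the synthetic generator's
  simplified physiology bound what desk-scale results can claim.
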