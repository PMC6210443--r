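---
title: "Channel-isolated CNNs for EEG band-power mental-task classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-isolated CNNs for EEG band-power mental-task classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcnn)
```

## The problem and the data

A subject alternates between three mental tasks -- left-hand motor imagery,
right-hand motor imagery, and word generation (class codes 2, 3 and 7) --
while EEG is recorded from eight centro-parietal electrodes (C3, Cz, C4, CP1,
CP2, P3, Pz, P4). The recording is distributed as *precomputed features*: a
power spectral density estimate in twelve 2 Hz sub-bands spanning 8--30 Hz
per electrode, written every 62.5 ms (16 frames per second). Each frame is
therefore a 96-vector (8 electrodes x 12 sub-bands); training files carry the
task code as a 97th column. Sessions last about four minutes and the task
switches every 15 s. `eegcnn` classifies these frames with a convolutional
network whose defining property is *channel isolation*: every
(electrode, sub-band) pair is processed by its own convolution stack, with no
data flow between channels until the fully connected head.

The physiological rationale: motor imagery modulates band power (mu/beta
event-related desynchronization) in a spatially and spectrally specific way,
and EEG channels carry heavily channel-specific noise. Convolving each
band-power stream separately filters that noise without mixing it across
channels, and leaves the cross-channel composition to the dense head.

## Architecture

An input window is a `96 x W` matrix of W consecutive frames (W = 16 frames
= 1 s by default; W = 8 = 0.5 s matches the half-second response-time
constraint common in online BCI protocols). The layers, with per-channel shapes for W = 16:

1. **Slicer** -- splits the window into 96 independent `1 x 16` streams
   (`slice_window()`).
2. **Conv1** -- 50 filters of width 5, stride 1 (`conv1d()`): `(50, 16)`.
3. **Conv2** -- 20 filters of width 3 over the 50 maps, directly stacked,
   with no pooling in between: `(20, 16)`.
4. **Pool** -- max over *adjacent pairs of feature maps*; the time axis is
   untouched (`pool_feature_maps()`): `(10, 16)`. This pools the feature-map
   axis rather than time -- unusual, but it is what the published
   layer-by-layer output dimensions specify, and it acts as a feature
   amplifier rather than a downsampler.
5. **ReLU**, then concatenation of all 96 channels: 15,360 features.
6. **Dense 96 with sigmoid**, **dense 3**, **softmax**.

Two printed specifications conflict: the convolution mode is listed as
"valid", yet every listed output keeps time length 16. We treat the shape
chain as the binding statement and default to zero-padded same-length
convolution (`padding = "same"`); `"valid"` remains available. Filters are
independent per channel (the parameter listing counts 96 x 50 first-layer
filters); `shared_filters = TRUE` ties one bank across channels for
ablation. Even kernel widths (which the hyperparameter scan generates, e.g.
4) are allowed with asymmetric same-padding and a warning.

## Training

* **Initialization**: all weight arrays use MSRA (He) draws, variance
  2/fan-in (`msra_init()`); biases start at zero. Because the output layer
  is also random, the balanced-batch loss starts slightly above ln 3 (by
  about half the variance of the class scores) rather than at ln 3 exactly.
  We evaluated a zero-initialized output layer, which does start at exactly
  ln 3, but rejected it: its first adaptive-gradient updates are
  sign-normalized outer products of a rank-one softmax residual with a
  shared hidden vector, leaving the output rows nearly collinear, and
  full-scale AdaGrad runs then settled into a constant-prediction basin.
  The random output layer breaks that degeneracy.
* **Loss**: mean softmax cross-entropy; gradients are exact analytic
  backpropagation, including max-pool routing (ties to the lower map index)
  and ReLU gating, verified against central finite differences in the test
  suite.
* **Schedules** (`lr_schedule()`/`lr_at()`): fixed, step, exp, poly, sigmoid
  with the published constants (base rate 0.01, gamma 0.75, stepsize 500,
  15,000 iterations, power 2). Two quirks are preserved as printed: the exp
  schedule with gamma 0.75 underflows to a vanishing rate within about 100
  iterations (the package logs a note), and the sigmoid schedule *rises*
  with the iteration count toward the base rate -- despite schedules being
  described as decreasing -- reaching exactly half the base rate at
  `i = stepsize`.
* **Solvers**: AdaGrad (per-weight accumulated squared-gradient history,
  epsilon 1e-8 added outside the root, so the first step with any non-zero
  gradient has magnitude exactly the learning rate and constant gradients
  give steps of lr/sqrt(t)), and momentum SGD (buffer
  `mu * buffer + lr * g`, default momentum 0.9).
* **Loop** (`cnn_train()`): one iteration is one minibatch update (the
  convention under which stepsize 500 and 15,000 iterations are meaningful);
  batch size defaults to 64 windows, shuffled each epoch under the run seed.
  Training accuracy at checkpoints is measured on a fixed subsample of at
  most `eval_train_max` training windows to keep checkpoints cheap. Since
  accuracy typically peaks well before the final iteration, the best
  checkpoint's weights are returned alongside the final ones.
  `repeat_and_average()` implements the five-repeat averaging protocol.

Windowing choices the source leaves open, fixed here as defaults: stride 1
frame (so each frame beyond the first W-1 ends exactly one window and
per-frame effectiveness against the 97th label column is well defined), and
the window label is the label of its *last* frame (causal, as an online
system would be scored). Majority and pure-only (drop windows spanning a
task switch) policies are available for experiments.

## Hyperparameter scan

`modified_param()` implements the ceiling rule `ceiling(x * (1 + delta))`
for delta in {-0.50, -0.25, +0.25, +0.50}, giving first-conv sizes
{3, 4, 7, 8} from base 5, second-conv sizes {4, 5} from base 3, and dense
widths {100, 150, 250, 300} from base 200 (the scan's base configuration
uses the 200-wide hidden layer). "Accuracy progress change over training" is
not formally defined in the source; `run_scan()` implements it as the mean
difference (modified minus base) of test-accuracy checkpoints over matched
iterations, in percentage points rounded to integers -- a curve-level
comparison, matching the phrase "progress over training" rather than a
final-value comparison. Base and modified runs share seeds so
initialization noise cancels. Cells that cannot train are reported as failed
and the scan continues.

## Evaluation suite

`confusion_matrix()` uses predicted classes on rows and actual classes on
columns, in class order 2, 3, 7 -- the orientation of the published tables.
The overall success rate (`osr()`) is the trace over the total count.
`binarize_one_vs_rest()` reduces the 3-class matrix to TP/FP/FN/TN for one
class, and `roc_params()` derives ACC, TPR, TNR, PPV and NPV; a parameter
with a zero denominator is `NA` (undefined), never 0. Reported values are
rounded half-up to 4 decimals, the convention that reproduces the published
per-class tables from the published confusion matrix. `aggregate_roc()` uses
the sample (n-1) standard deviation -- confirmed by recomputing the
published dispersion of the three per-subject success rates (0.1301).
`effectiveness()` scores per-frame predictions against the label column,
excluding the first W-1 frames (no complete causal window) and reporting the
exclusion count. `generalization_error()` is training-phase accuracy minus
test accuracy in percentage points.

Two source-data caveats, documented rather than reconciled: the published
Subject 2 and Subject 3 confusion matrices are inconsistent with their
printed success rates (Subject 2's matrix sums to 3472, not 3504, and yields
0.7212 vs the printed 0.7216; Subject 3 yields 0.5619 vs 0.5571), so Subject
1 -- which is internally consistent -- anchors all verification; and the
printed worked-example success rate 0.8140 is a print-rounding artifact of
2852/3504 = 0.81393.

## The synthetic generator

`generate_session()` emulates the *structure* of the feature files so the
whole pipeline is testable without any recording: 16 frames/s, 4-minute
sessions, a uniformly random block schedule switching task every 15 s with
no immediate repetition, and strictly positive PSD values generated as
`exp(baseline + class_effect + AR(1) log-noise)`. Class effects imitate
motor-imagery physiology purely to make classes separable: left-hand imagery
attenuates right-hemisphere mu/low-beta channels (C4, CP2, P4), right-hand
imagery mirrors this on the left, and word generation raises parietal alpha
power. Defaults: effect magnitude 0.8, log-noise sigma 0.5 (marginal), AR(1)
coefficient 0.6 -- strong, frame-separable effects, which is what the
end-to-end classifier checks require.

The baseline log-power is set so typical band powers are about 0.1. PSD
units are arbitrary, and this scale matters: the network applies no input
normalization, so the input scale directly sets the operating point of the
dense sigmoid layer. At band powers of order 10 the concatenated features
saturate the sigmoid at initialization and adaptive-gradient training
stalls, while momentum SGD still escapes; at order 0.1 both solvers train
normally. We fixed the default at the well-conditioned scale and note the
saturation behaviour here because real recordings in arbitrary units may
need rescaling before training.

What the generator does *not* emulate: raw EEG time series, realistic 1/f
spectra, artifacts (the original data ship without artifact rejection),
non-stationarity across sessions, or between-subject variability. Passing
tests on this generator therefore demonstrate that the pipeline learns and
scores class-conditional band-power structure, not that any particular
accuracy transfers to recorded data.

## Problem sizes and numerical choices

The test suite trains the full 96-channel network on the generator's default
conditions (three 4-minute training sessions, one test session, 2000
iterations at batch 64) and checks that the best checkpoint exceeds 80% test
effectiveness while permuted labels stay at chance; unit tests use miniature
configurations (2--8 channels) so brute-force oracles and finite differences
stay exact and fast. Other numerics: softmax and its loss use log-sum-exp
with max subtraction; exact probability ties in prediction resolve to the
lowest class code; AdaGrad's epsilon sits outside the square root; max-pool
gradient ties go to the lower map index; feature files are written with 10
significant digits, which round-trips beyond the 6 significant digits the
I/O contract promises.

## Limitations

The two figure-only architecture variants of the source (the AlexNet/VGG-16
style multichannel adaptations and the adapted single-class topology) are
out of scope -- their layer parameters are not recoverable from text -- as
are AdaDelta and Adam, raw-EEG preprocessing (surface Laplacian, PSD
estimation), and score-threshold ROC curves/AUC (the evaluation reports
point parameters only). Published headline effectiveness values depend on
the original recordings and unrecorded seeds and are not reproduction
targets; the package's verifiable surface is the worked-example metrics, the
closed-form schedule and solver identities, the ceiling rule, and the
property-based checks above.
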