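# eegcnn

Classification of mental tasks from EEG band-power features with
channel-isolated convolutional networks.

## The problem

In a brain–computer interface (BCI) setting, a subject alternates between
three mental tasks — left-hand motor imagery, right-hand motor imagery, and
word generation (class codes 2, 3, 7) — while EEG is recorded from eight
centro-parietal electrodes (C3, Cz, C4, CP1, CP2, P3, Pz, P4). The data
arrive as precomputed features: a power-spectral-density estimate in twelve
2 Hz sub-bands (8–30 Hz) per electrode, written 16 times per second, i.e.
one 96-vector per 62.5 ms frame, with the task code as a 97th column in
labelled files. The goal is to classify every frame.

`eegcnn` implements a convolutional network built around *channel
isolation*: each of the 96 (electrode, sub-band) channels is convolved
independently — a slicer splits the `96 × W` input window (W = 16 frames =
1 s by default) into 96 streams, each passing through two stacked 1-D
convolutions (50 filters of width 5, then 20 of width 3, per channel,
stride 1, `f(x,y) = Σ_{i,j} a_ij · b_{x+i, y+j}`), a max pool over
*adjacent feature-map pairs* (20 → 10 maps, time untouched) and a ReLU.
Only then are the channels concatenated and decoded by a dense sigmoid
layer (96 units) and a 3-class softmax. The package also provides the full
training stack (MSRA initialization, exact backpropagation, AdaGrad and
momentum SGD, the five learning-rate schedules `fixed`, `step`, `exp`,
`poly`, `sigmoid` with base rate 0.01, γ = 0.75, stepsize 500), the
one-factor hyperparameter scan with ceiling rounding
`p_Δ(x) = ⌈x(1 + Δ)⌉`, a one-vs-rest multi-class ROC evaluation suite
(overall success rate = trace of the confusion matrix over N, per-class
ACC/TPR/TNR/PPV/NPV, generalization error), a synthetic PSD session
generator, and readers/writers for the whitespace-delimited feature files.

## Worked example

```r
library(eegcnn)

# simulate a subject: three labelled training sessions + one test session
ds <- generate_dataset(generator_config(session_minutes = 1, seed = 5))
ds$train[[1]]
#> <psd_session> 960 frames (60.0 s at 16 Hz), labelled, subject synthetic/train_1
#>   classes: 2=240 3=240 7=480

# train the channel-isolated CNN (1-s windows, AdaGrad, step schedule)
rec <- cnn_train(ds$train, ds$test, max_iter = 500, eval_every = 125, seed = 2)
rec
#> <train_record> adagrad solver, step schedule, 500 iterations (seed 2)
#>   final: train 0.9982, test 0.9905; best test 0.9905 at iteration 500

# score the test session frame by frame
report <- evaluate_session(rec$best_weights, ds$test[[1]])
report$confusion
#>          actual
#> predicted   2   3   7
#>         2 462   3   1
#>         3   0 235   0
#>         7   3   2 239
round(report$effectiveness$percent, 2)
#> [1] 99.05
```

The confusion matrix counts predicted classes on rows against actual
classes on columns; `effectiveness` is the percentage of frames whose
prediction matches the label column (the first W − 1 = 15 frames have no
complete causal window and are excluded). `report$roc` adds the per-class
one-vs-rest parameters and the overall success rate.

The evaluation suite reproduces the published worked example from its
printed confusion matrix:

```r
cm <- matrix(c(905, 213, 61, 64, 725, 157, 71, 86, 1222), 3, byrow = TRUE,
             dimnames = list(predicted = c(2, 3, 7), actual = c(2, 3, 7)))
osr(cm)
#> [1] 0.8139269
roc_params(binarize_one_vs_rest(cm, 2))
#>       ACC       TPR       TNR       PPV       NPV
#> 0.8832763 0.8701923 0.8887987 0.7675997 0.9419355
```

A thin command-line dispatcher over the same functions is installed at
`inst/cli/eegcnn.R` (`simulate`, `train`, `evaluate`, `parmod-scan`,
`lr-table`), configured by a YAML file whose defaults are the published
values.

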