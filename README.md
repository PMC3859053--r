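# arhar

Autoregressive-coefficient features and kernel discriminant analysis for
smartphone-based human activity recognition.

## The problem

A phone in a pocket records triaxial acceleration that mixes the wearer's
motion with gravity. Recognizing everyday activities (standing, walking,
walking up/down stairs, running, hopping) *on the device* demands features
that stay accurate at a low sampling rate (20 Hz) and a short data window
(3 s) — the settings that keep battery drain and response latency low.
Activity acceleration signals show strong positive autocorrelation (lag
plots hug the diagonal; autocorrelation decays slowly), i.e. they behave
like realizations of an autoregressive (AR) process

    x[n] = a_1 x[n-1] + ... + a_M x[n-M] + e[n],

so the per-axis AR coefficients are a natural compact feature: with model
order p = 10 per axis, each 3-s window becomes a 30-dimensional vector
`[a_x1..a_x10, a_y1..a_y10, a_z1..a_z10]`.

Two standard complications are handled around that core idea:

* **Model identification.** The order M is chosen by minimizing the Akaike
  information criterion `AIC = -2 L_m + 2m` averaged over the three axes;
  the window length is chosen from the plateau of the model-fit SNR
  `10 log10( sum v^2 / sum (v - vhat)^2 )`; the fitted model is accepted
  only if its held-out one-step residuals look like white noise
  (autocorrelations inside the `±1.96/sqrt(N)` band).
* **Phone position.** The same activity recorded from a different pocket
  produces a different signal, inflating within-class variance. Kernel
  discriminant analysis (KDA) with an RBF kernel maximizes
  `J(alpha) = (alpha' K W K alpha)/(alpha' K K alpha)` via the generalized
  eigenproblem `K W K alpha = lambda K K alpha` and projects the 30-dim
  features onto the `C - 1 = 5` most discriminating directions before a
  small `[5, 3, 6]` feed-forward neural network assigns the activity.

A built-in synthetic generator emulates the study design (multiple
subjects, 6 activities, 5 phone placements, 20 Hz) with stable per-activity
AR processes plus gravity, so the whole pipeline is testable without any
recorded data.

## Worked example

```r
library(arhar)

# 5 training subjects and 3 disjoint evaluation subjects;
# 6 activities x 5 phone positions x 30 s sessions at 20 Hz
train_corpus <- generate_dataset(generator_config(n_subjects = 5, seed = 11))
eval_corpus  <- generate_dataset(generator_config(n_subjects = 3, seed = 11,
                                                  subject_offset = 5))

bundle <- train_pipeline(train_corpus, har_config(seed = 11))
print(bundle)
#> <har_bundle> 6 classes, AR order 10, KDA d = 5, ANN [5-3-6]

cm <- evaluate_pipeline(bundle, eval_corpus, subject_independent = TRUE)
print(cm)
#> <har_confusion> 900 windows (row-normalized %)
#>                     predicted
#> true                 hopping running standing walking walking-downstairs walking-upstairs
#>   hopping               96.7     0.0      2.0     1.3                0.0              0.0
#>   running                0.0    91.3      1.3     7.3                0.0              0.0
#>   standing               0.7     0.0     99.3     0.0                0.0              0.0
#>   walking                0.7     4.7      0.0    90.0                0.0              4.7
#>   walking-downstairs     1.3     0.0      0.0     0.0               98.7              0.0
#>   walking-upstairs       1.3     0.7      0.0     2.7                0.0             95.3
#> Mean 95.2
```

Rows are true activities, columns predictions, entries row percentages; the
`Mean` line is the unweighted mean of the diagonal (mean per-class recall).
Here 900 windows from three never-seen subjects are classified with 95.2%
mean accuracy; the residual confusions sit between the gait activities with
neighboring cadences (walking vs. running and walking-upstairs), as
expected.

Window-by-window (online) classification of a single recording:

```r
head(classify_stream(bundle, eval_corpus[[1]]), 3)
#>   window    label    hopping     running  standing      walking ...
#> 1      1 standing 0.01162945 0.005284853 0.9802985 1.281557e-05
#> 2      2 standing 0.01391636 0.004297733 0.9789341 1.170953e-05
#> 3      3 standing 0.01843423 0.004275126 0.9743109 1.506246e-05
```

A thin command-line wrapper around these functions ships in `inst/cli/arhar`
(subcommands `generate`, `select-order`, `select-window`, `train`,
`evaluate`, `classify`, `ablate-kda`, `eda-export`).

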