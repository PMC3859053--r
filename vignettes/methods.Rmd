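---
title: "Methods: AR-coefficient features, kernel discriminants, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AR-coefficient features, kernel discriminants, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arhar)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the bundled synthetic data can show. It is
the package's design record: everything empirical it refers to is computed
by the test suite or by `scripts/acceptance.R`, not asserted here.

## Signal model and preprocessing

A pocketed phone's accelerometer reports, per axis, the sum of a slowly
varying gravity component and the wearer's motion. Gravity is estimated by
exponential smoothing, `g[n] = alpha * g[n-1] + (1 - alpha) * a[n]`, and
subtracted. The weight `alpha` (unitless, in `[0, 1)`, default **0.8**) sets
the tracking time constant: at 20 Hz, 0.8 corresponds to a ~0.2 s
equivalent averaging window — slow enough that gait-band motion (0.5–4 Hz)
survives subtraction almost intact, fast enough to follow posture changes.
The filter is initialized at `g[1] = a[1]`: a constant input then yields
exactly zero output from the first sample, with no burn-in artifact.

Impulsive noise is reduced with a **causal** moving average of order 3
(samples). The causal form (current plus two previous samples) is what a
streaming classifier can compute in real time; the first two samples
average over the shorter available prefix rather than being padded.
Gravity removal runs before smoothing — the gravity estimate should see
the rawest signal — though at these filter lengths the order is not
critical.

Windows of `window_seconds` (default **3 s**, i.e. 60 samples per axis at
20 Hz) are cut without overlap by default; the step is
`round(N * (1 - overlap_fraction))` and a trailing partial window is
discarded. A recording shorter than one window yields an empty window
list, not an error, so streaming callers need no special casing.

## AR features and model identification

Each axis of a window is modeled as an AR(M) process. Coefficients are
estimated with **Burg's maximum-entropy lattice recursion**, which
minimizes the combined forward/backward prediction-error power stage by
stage. Burg is preferred over least squares here for two reasons: it is
numerically cheap on short windows (60 samples), and every reflection
coefficient lies in (−1, 1), so fitted models are always stable — which
matters because the package also simulates from fitted models. The test
suite cross-checks the implementation against `stats::ar.burg` (agreement
to 1e−3) and against Yule–Walker closed forms.

**Order selection.** For candidate orders, the Gaussian conditional
likelihood from the Burg residual variance gives
`AIC = n(log(2*pi*sigma2) + 1) + 2m` with parameter count
`m = order + 1` (coefficients plus innovation variance). Scores are
averaged over the three axes and over windows. Two rules are provided:
`min` (argmin, ties toward the smaller order) and `elbow` (the smallest
order improving on its predecessor by less than 1% relative — a
codification of "the curve evens out"). The constant likelihood terms are
retained; they cancel in every comparison at fixed `n`.

**Window-length selection.** For each candidate window length, an
order-10 model is fitted per axis and the fit quality is summarized as
`SNR = 10 log10(sum v^2 / sum (v - vbar)^2)` in dB. A subtlety: comparing
the original sample-by-sample against an *independently simulated*
realization is ill-posed (an independent realization shares no sample
alignment with the data), so `vbar` is the **deterministic one-step
prediction sequence** of the fitted model. The selected length is the last
candidate *before* the first relative SNR gain below 1% — the shortest
window already delivering essentially the full fit quality, which is the
right operating point for a system whose response latency equals the
window length. A curve that keeps improving selects the largest candidate.
Note that at 20 Hz a 1-s candidate (20 samples) cannot support an order-10
fit (Burg needs `> 2M` samples); `select_window_length` rejects such
candidates explicitly rather than guessing a different sampling rate.

**Validation.** A fitted model is checked on *held-out* data: one-step
residuals are computed on a different sample from the same source and
tested for whiteness. The whiteness rule — normalized, demeaned
autocorrelation at lags 1..20 compared against `±1.96/sqrt(N)`, verdict
"white" when at most 10% of lags fall outside — is this package's
codification of a residual-diagnostic practice that is usually judged by
eye. Its operating characteristics follow from binomial arithmetic: an
exactly white series lands outside the band with probability ≈ 0.05 per
lag, so the pass probability is ≈ `P(Binom(20, 0.05) <= 2)` ≈ 0.92, and
the test suite asserts a conservative ≥ 0.85 pass rate for i.i.d. noise.
The acceptance-level check fits order-10 models on 4000-sample
realizations and validates on 500-sample held-out stretches: the larger
fitting sample keeps coefficient estimation error well below the width of
the held-out confidence band, and the biased (1/N) autocorrelation
estimator shrinks high-lag values slightly, both of which keep matched
models near the ideal pass rate while order-1 misfits fail essentially
always. A constant (zero-variance) series is degenerate and reported
not-white with `fraction_outside = 1`.

The per-window feature vector concatenates the three per-axis coefficient
vectors, x then y then z: `3p = 30` dimensions at the default `p = 10`.

## Kernel discriminant analysis

AR coefficients at different lags live on different scales, so features
are z-scored with training statistics before kernel evaluation. The RBF
bandwidth `gamma` defaults to the median heuristic
`1/(2 * median(pairwise distance)^2)`, overridable.

The discriminant directions maximize
`J(alpha) = (alpha' K W K alpha)/(alpha' K K alpha)`, solved as the
generalized eigenproblem `K W K alpha = lambda (K K + eps I) alpha` via
Cholesky whitening of the (ridge-regularized) right-hand matrix followed
by a symmetric eigendecomposition. Three numerical choices deserve
explanation:

* **Globally centered indicator.** The raw class-indicator matrix
  (`1/m_k` blocks) is a projector, so *every* direction whose kernel image
  is constant within classes — including the useless global-constant
  direction — attains the maximal eigenvalue. The between-class scatter is
  therefore built around the global mean: `W <- indicator - 1/m`, whose
  quadratic form is exactly `sum_k m_k (mean_k - mean)^2` of the projected
  values. Without this, the leading retained component carries no class
  separation (measured directly in the test suite via Fisher ratios).
* **Ridge scaling.** `K K` is rank-deficient in practice. The default
  ridge is `eps = 1e-8 * trace(KK)` — proportional to `trace(KK)` alone,
  not `trace(KK)/m`, because duplicating every training sample maps the
  eigenproblem onto itself with ridge `eps/4` while `trace(KK)` grows
  4-fold: this scaling (and no other m-dependence) makes projections
  exactly invariant under dataset duplication, a property the test suite
  checks at 1e−6.
* **Normalization and sign.** Each `alpha` column is scaled so its basis
  vector has unit norm in feature space (`alpha' K alpha = 1`) — again the
  duplication-invariant convention — with the first non-negligible entry
  made positive for reproducibility. Retained components are capped at
  `C - 1 = 5`, the rank of the between-class operator.

New patterns are projected as `alpha' [K(x_1, x), ..., K(x_m, x)]'`.

## Classifier

The classifier is a `[d, 3, C]` feed-forward network: logistic hidden
units, softmax output, cross-entropy loss, mini-batch gradient descent.
Defaults: learning rate 0.1, 500 epochs, batch size 32, hidden size 3 —
standard settings for a network this small; all are configuration knobs.
The classifier inputs — KDA projections, or raw AR features when KDA is
disabled — are z-scored with training statistics before training and at
prediction time: the projections' natural scale is far below 1 under the
unit-basis-vector normalization, and unit-scale inputs keep gradient steps
effective regardless of corpus size. Weights initialize from seeded
uniform(−0.5, 0.5) and the per-epoch shuffle draws from the same seeded
stream, so training is bit-reproducible given the seed. Ties in the argmax break toward the lower class index.
Models and whole pipeline bundles persist as JSON with numeric arrays
written as 17-significant-digit strings, because standard JSON numeric
output loses the last bit of an IEEE double and the persistence contract
here is bit-exact reproduction of predictions.

## The synthetic study design

The generator exists so that every stage — preprocessing, identification,
validation, discriminant analysis, classification — can be exercised and
tested without any recorded data. It emulates the *statistical structure*
the analysis assumes, not biomechanics:

* **Activities** are order-10 AR processes per axis, built by pole
  placement: one lightly damped conjugate pair at an activity-specific
  cadence frequency (walking 1.0 Hz, walking-upstairs 0.7, walking-downstairs
  1.4, running 2.3, hopping 3.1; dominant pole modulus 0.96–0.975, slightly
  detuned per axis) plus four background pairs with moduli 0.55–0.80.
  Standing is low-power, weakly correlated postural sway (dominant modulus
  0.55, innovation variance ~0.004 vs 0.25–0.9 for locomotion). The
  background-pole strength is a fixture-design constraint: all ten
  coefficients must carry enough signal that order identification can
  recover p = 10 at n = 2000, the recovery property the acceptance target
  measures.
* **Gravity** enters as a constant `9.81 * unit orientation` per activity,
  so gravity removal has real work to do.
* **Positions** are fixed affine distortions — a rotation (8° to ~60°
  composite angles across the five pockets), per-axis gains 0.9–1.1, and
  constant offsets — applied to the motion signal. Two recordings of the
  same activity from different pockets therefore differ substantially
  while sharing a label: exactly the within-class variance KDA is meant to
  suppress, and the test suite verifies that the within/between scatter
  ratio shrinks under projection and that ablating KDA costs accuracy.
* **Subjects** perturb the AR coefficients multiplicatively (5% relative
  jitter by default), with poles reflected back outside the unit circle if
  a perturbation destabilizes them. Per-recording seeds derive
  deterministically from the master seed.

Default corpus shape: 5 training subjects, 3 disjoint evaluation
subjects, 6 activities, 5 positions, 30-s sessions (ten 3-s windows) at
20 Hz — 150 training and 90 evaluation recordings, 1500/900 windows.
These sizes keep a full train/evaluate cycle under a minute on one core
while leaving enough windows per class for stable confusion matrices.

What passing tests on this corpus do **not** show: the generator's classes
are genuinely AR with distinct spectra, so separability is built in by
construction. Results on it validate the *machinery* (estimators,
eigensolver, training loop, protocol enforcement), not real-world
recognition accuracy. Real gait signals are nonstationary within windows,
share cadence across activities far more than these profiles do, and vary
across subjects in ways 5% coefficient jitter does not capture. The
subject-independent accuracy floor asserted in the tests (≥ 80% mean
per-class recall) is a smoke-level guarantee of pipeline health, not a
claim about human data.

## Evaluation conventions

Evaluation is per window — no majority voting across windows — and the
confusion matrix is pooled over all evaluated windows, with rows
row-normalized to percentages. The headline number is the **unweighted
mean of the diagonal** (mean per-class recall over non-empty rows), the
convention under which a published diagonal reproduces its published mean.
Subject-independence is enforced by the harness: `evaluate_pipeline(...,
subject_independent = TRUE)` refuses any overlap between evaluation
subjects and the subjects recorded in the training bundle.

## Known limitations

* The whiteness rule's thresholds (band multiplier 1.96, 20 lags, 10%
  exceedance) are conventional, not optimized; its false-pass rate for
  mildly structured residuals has not been characterized.
* The kernel matrix is not centered in feature space (only the class
  indicator is globally centered); with strongly unbalanced classes the
  two choices can differ, and the package has only been exercised on
  balanced corpora.
* `fit_kda` stores the full training set and `project_kda` is O(m) per
  query; no low-rank approximation is provided, so very large corpora
  (m ≫ 10^4 windows) would need subsampling.
* The generator does not model sensor saturation, sampling jitter,
  missing samples, or within-session position shifts; recordings are
  stationary by construction.
* Resampling across sampling rates is out of scope; recordings are
  validated to be uniformly sampled within 10% of the nominal rate.
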