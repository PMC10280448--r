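---
title: "Forecasting missing impedance-cardiography characteristic points with a NARX network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting missing impedance-cardiography characteristic points with a NARX network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgnarx)
```

## The problem

Impedance cardiography (ICG) measures thoracic impedance changes tied to
cardiac function; the first derivative dZ/dt of one heartbeat is annotated by
seven characteristic landmarks (A, B, E, X, Y, O, Z), with two competing
candidates X1 and X2 for the X point in some morphologies. Hemodynamic
parameters such as the left ventricular ejection time (the B-to-X interval)
and, downstream, stroke volume and cardiac output depend on these landmarks,
but in beat-to-beat recordings the complex morphology varies systematically.
The atypical subtypes (ABEXYOZ1--5) lack specific points -- the ABE points
and the YOZ points tend to appear and disappear as groups -- and the
ABEXYOZu subtype carries no detectable points at all. Averaging beats hides
this variability; working beat to beat leaves a large fraction of landmarks
undetected.

`icgnarx` addresses the gap with a time-series predictive model. Every beat
is reduced to nine intervals anchored at the ECG R peak: the RR interval and
the R-to-point latencies (RA, RB, RE, RX1, RX2, RY, RO, RZ). A nonlinear
autoregressive network with exogenous inputs (NARX) is trained on the typical
(ABEXYOZ0) beats, where all landmarks are observed, and then run along the
atypical beat streams to forecast the latencies of the missing points.

## The interval representation

`build_interval_matrix()` turns annotated beats into a beats-by-9 matrix.
RR(i) is defined as the forward interval `r_time(i+1) - r_time(i)` and each
subject's last beat is dropped: the point columns are later divided by RR of
the same row, and the forward convention keeps every latency inside its own
RR window. Latencies of absent points are missing values. One time-series
stream is formed per (dataset, subject, subtype) -- the matrix is built per
subtype per volunteer -- and no delay line ever crosses a stream boundary.

Preprocessing follows three steps:

1. **Mean imputation** (`impute_missing_means()`): a missing cell is replaced
   by the mean of the available cycles of the same column, grouped by
   (dataset, subject, subtype), falling back to the same-dataset column mean
   when the group has no observation. Grouping by subject and subtype first
   preserves subject-level latency structure. Imputation happens on raw
   intervals, before normalization, fixing the order of the two operations;
   the returned mask records exactly which cells the network must later
   forecast.
2. **RR normalization** (`normalize_rr()`): each point column is divided
   row-wise by RR, removing between-subject heart-rate differences. The RR
   column itself stays in seconds so the transform can be inverted.
3. **Sum-of-squares normalization** (`normalize_sum_squares()`): each point
   column is scaled to unit sum of squares over the pooled rows of *all*
   datasets, so one model fits data from different acquisition systems. The
   scale factors are persisted with the model and re-applied to new data
   rather than renormalized, and invert the transform to round-off
   (`denormalize()` recovers seconds to 1e-12).

## The network

The model is a NARX network with eight input and eight output channels (the
eight RR-ratio latencies), one hidden layer of ten hyperbolic-tangent units,
a linear output layer, and delay taps {1, 2} on both the exogenous and the
feedback line:

```
y_hat(t) = W_o tanh( W_x [x(t-1); x(t-2)] + W_y [y(t-1); y(t-2)] + b_h ) + b_o
```

Because the same eight ratio channels serve as both inputs and outputs, the
exogenous line carries the same series as the target (`x = y`), making the
model an order-2 nonlinear autoregression with duplicated tap banks -- the
only reading consistent with an 8-in/8-out configuration on a single feature
set. Weights are initialized Nguyen-Widrow style (seeded), which spreads the
hidden units across the active region of the tanh; a plain uniform
initialization is available.

Two loop modes exist. **Open loop** (series-parallel) feeds the true past
targets into the feedback taps -- teacher forcing -- which makes every time
step an independent feed-forward sample, so training needs no
backpropagation through time and the residual Jacobian is exact
(`narx_jacobian()`, verified against central finite differences to a relative
error below 1e-5). **Closed loop** (parallel) feeds the network its own past
predictions for free-running multi-step forecasts. `narx_remove_delay()`
shifts the taps from {1, 2} to {0, 1}, so the fitted network emits each
forecast one step ahead of the original alignment; the weights are untouched.
We implement pure tap shifting (the delay-line states are not prepended), and
note that on a recorded stream the removed-delay network computes the same
values one index earlier -- imputation results are therefore
alignment-invariant.

## Training

`narx_train()` trains full batch (the data sizes are hundreds of rows) under
one of three algorithms:

* **Levenberg-Marquardt** (`"lm"`): damped Gauss-Newton steps
  `(J'J + mu I) dw = J'e`, with `mu` multiplied by 10 on a rejected step and
  by 0.1 on acceptance (defaults `mu0 = 1e-3`; all configurable). Training
  loss never increases at an accepted step; `mu` above 1e10 aborts the epoch.
* **Scaled conjugate gradient** (`"scg"`): Moller's algorithm on the
  sum-of-squares loss, using only gradient evaluations (the Hessian-vector
  product is approximated by a finite difference of gradients) -- no
  Jacobian is materialized, which is the memory-saving option.
* **Bayesian regularization** (`"br"`): the LM engine on
  `F = beta SSE/2 + alpha |w|^2/2`, re-estimating `alpha` and `beta` each
  epoch from the effective number of parameters
  `gamma = N_w - alpha tr((beta J'J + alpha I)^-1)` (MacKay evidence
  updates). Validation stopping is disabled by default for this algorithm --
  the evidence term takes its role -- and can be re-enabled. With `alpha`
  fixed at zero the trajectory reduces exactly to plain LM.

Teacher-forced samples are split 70/15/15 into training, validation and test
sets by a uniformly random, seeded permutation of rows (floor for train and
validation, remainder to test). The split unit is the beat, mirroring random
division of input vectors; a grouped (subject-level) split mode is available
for leakage-aware evaluation but is not the default. Early stopping monitors
the validation loss with a patience of 6 epochs and always restores the
weights of the best validation epoch. The loss is the mean squared error
over all eight channels jointly, unweighted. All randomness -- weight
initialization and the split -- flows from one seed.

`compare_algorithms()` trains all three from identically seeded weights and
ranks by higher VEcv on the shared test partition, breaking ties by lower
RMSE and then declaration order.

## Forecasting and X selection

`impute_missing_points()` runs an observation-aware closed loop along each
stream: every tap reads the observed value where one exists and the
network's previous prediction where it does not. Pure free running would
discard usable observations in partially observed beats, which is why the
hybrid mode is the default (and only) imputation mode. Missing values inside
the initial delay horizon are seeded with the training-set channel means.
Observed cells are never overwritten (a bit-level guarantee), ABEXYOZu
streams are flagged unforecastable, and the first two beats of every stream
-- inside the delay horizon -- are flagged likewise and left untouched.
Imputation runs forward in time only. The one-step predictions at observed
cells double as a held-out accuracy check, reported per subtype.

`select_x()` decides, per dataset and subtype, which X candidate to use: it
computes the root-mean-square deviation of each candidate's RR ratio from
the mean reference ratio of that candidate in the typical beats of the same
dataset and picks the smaller. RMS about the *reference* (rather than a
standard deviation about the candidate's own mean) makes a fixed
displacement of the spurious candidate detectable. Ties go to X2, the true X
of typical complexes. Selection is per-scope because different acquisition
systems can favor opposite candidates.

## Evaluation metrics

`eval_report()` reports, pooled over channels and per scope (dataset,
subtype, or point): MSE, RMSE, MAE, Pearson R, VEcv and Lin's concordance
correlation coefficient. VEcv is the variance explained by cross-validation,
`100 (1 - SSE/SStot)`, at most 100 and negative when the prediction is worse
than the target mean; its performance bands are very poor (<= 10), poor
(10, 30], average (30, 50], good (50, 80] and excellent (> 80), upper
boundaries inclusive. Lin's CCC uses population (1/n) moments, its original
definition; Pearson R is a moment ratio and invariant to that choice.
`detection_rates()` converts missingness percentages before/after
imputation into detection percentages and computes the effective rate --
fully detected complexes over all complexes excluding ABEXYOZu, which has
nothing to detect. Every metric is tested against an independent brute-force
implementation on a thousand random pairs to 1e-10.

## The synthetic cohort generator

The recordings such a model is built for are rarely shareable, so
`generate_cohort()` provides a fully synthetic test bed. Per subject, RR
follows a stationary AR(1) process around the device's mean; each point
latency ratio is

```
ratio(P, i) = mu_P (1 + g_s) + lambda_P c_i + mu_P sigma_eps eps
```

with a relative subject effect `g_s`, a standardized AR(1) beat factor `c_i`
shared across points (so channels are cross-correlated and a delay-2
forecaster has signal to learn -- the autocorrelation is our addition, with
coefficient 0.6 by default), and white per-point noise. Default latency
means (A 0.05, B 0.10, E 0.18, X1 0.30, X2 0.38, Y 0.50, O 0.62, Z 0.75 as
RR fractions) respect the within-beat point order; they are order-respecting
conventions, not measured values, and fully configurable. Subtypes are drawn
independently per beat; each subtype masks a fixed point set, with ABE and
YOZ masked as groups. One candidate (X2 by default) carries the clean
latency process; the other is displaced by a fixed bias in atypical
complexes, emulating a morphologically displaced spurious candidate. The
exact per-subtype missing-point sets of real recordings are not published in
detail, so the defaults follow the group behavior and are user-overridable.

`default_cohort_config()` describes two 4-subject cohorts with distinct RR
means (0.85 s and 0.70 s, emulating two devices), an imbalanced subtype mix,
and heavy X/YOZ missingness (~55% and ~60% of beats). With 100 beats per
subject this gives 792 interval rows -- small enough that the complete test
suite and the acceptance script run in seconds, large enough for stable
metric estimates.

What passing tests on this generator do **not** show: real dZ/dt morphology,
detection errors upstream of annotation, non-stationary rhythms
(arrhythmias), or missingness that is informative of the latency values.
The generator's missingness is determined by the subtype alone.

## Numerical choices and degenerate inputs

* Sum-of-squares scales must be strictly positive; a zero-norm column is an
  error, as is applying a normalization out of state order (each
  `interval_matrix` carries its normalization state and every transform
  guards it).
* A subject with a single beat has no RR interval and is skipped with a
  warning; non-positive RR or a non-positive latency is an error naming the
  row.
* Splits need at least 10 rows; below that the 70/15/15 partition
  degenerates.
* The LM damping is capped at 1e10 (stop reason `mu_overflow`); the BR
  effective-parameter count is clamped to [0, N_w] with a warning; SCG
  signals non-finite losses.
* Streams shorter than three beats cannot be forecast and are flagged
  rather than silently dropped.
* X-selection ties go to X2; scopes with fewer than two complete rows are an
  error rather than a silent NA.

## Known limitations

* Gradients are exact only under teacher forcing; there is no
  backpropagation through the closed loop, so closed-loop error is evaluated
  but never directly minimized.
* Imputation quality on channels that are missing for an entire stream rests
  on cross-channel structure; if the channels were independent, the network
  could do no better than the conditional mean.
* The package consumes already-annotated points; detecting characteristic
  points from raw dZ/dt waveforms and classifying subtypes are upstream
  problems out of scope, as is computing LVET, stroke volume or cardiac
  output from the completed points.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 1,
                         train = list(algorithm = "lm", max_epochs = 60)))
res$evaluation$detection$effective
res$selection
```

The evaluation list reports open-loop test metrics per dataset, held-out
one-step metrics per subtype, detection rates before and after imputation,
and -- because the default input is synthetic -- the imputed-vs-truth
accuracy on exactly the cells that were masked. `scripts/acceptance.R` runs
this same computation end to end and writes the headline numbers to JSON.
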