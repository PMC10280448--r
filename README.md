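# icgnarx

Forecasting missing characteristic points in beat-to-beat impedance
cardiography (ICG) with a NARX recurrent neural network.

## The problem

The dZ/dt ICG complex of one heartbeat is annotated by seven characteristic
landmarks — A, B, E, X, Y, O, Z (with two competing candidates X1/X2 for the
X point) — from which hemodynamic parameters such as the left ventricular
ejection time (B-to-X) are computed. In beat-to-beat analysis the complex
morphology varies across subtypes (ABEXYOZ0 typical, ABEXYOZ1–5 atypical,
ABEXYOZu without any detectable points), and entire point groups (ABE, YOZ)
go missing together, leaving a large fraction of landmarks undetected.

`icgnarx` represents each beat by its R-peak-anchored interval vector

```
(RR, RA, RB, RE, RX1, RX2, RY, RO, RZ)
```

normalizes the eight latencies as RR ratios and rescales each column to unit
sum of squares across datasets, and trains a nonlinear autoregressive
network with exogenous inputs (NARX) — 8 channels in and out, 10 hidden tanh
units, delay taps {1, 2} —

```
ŷ(t) = W_o · tanh( W_x [y(t−1); y(t−2)] + W_y [y(t−1); y(t−2)] + b_h ) + b_o
```

open-loop (teacher-forced) on the typical beats, by Levenberg–Marquardt,
scaled conjugate gradient, or Bayesian regularization, with validation-based
early stopping on a 70/15/15 split. The loop is then closed (optionally with
the delay removed) and run along each (subject, subtype) beat stream to
forecast the latencies of missing points; observed values are always kept
and fed back in preference to predictions. The suite of accuracy metrics —
MSE, RMSE, MAE, Pearson R, VEcv with its five performance bands, Lin's
concordance correlation coefficient, and detection/effective rates — plus a
per-dataset X1-vs-X2 candidate selector complete the workflow. A synthetic
cohort generator with subject effects, AR(1) beat-to-beat structure, subtype
mixing and grouped missingness provides a fully reproducible test bed.

## Worked example

```r
library(icgnarx)
res <- run_pipeline(list(seed = 1, train = list(algorithm = "lm", max_epochs = 60)))
res$model
#> <narx_model> 8 channels, 10 hidden tanh units, taps x{1,2} y{1,2}
#>   418 weights; trained: with normalization metadata
res$report
#> <narx_train_report> lm, 9 epochs, stopped: val_fail, best epoch 3
#>   final train MSE 1.75e-06; val MSE 3.31e-06
res$imputation
#> <imputation_result> 1516 cells imputed, 880 left missing (unforecastable rows: 176)
res$evaluation$detection$effective
#>   dataset_id effective_rate plain_rate
#> 1          S       90.83095   80.05051
#> 2          V       91.18457   83.58586
```

With no input file, the pipeline generates the default synthetic cohort (two
4-subject datasets, 100 beats each), trains on the ABEXYOZ0 streams, and
imputes every cell that was missing. The 1516 imputed cells are the
latencies the network forecast; the 880 cells left missing all sit in
unforecastable rows (ABEXYOZu beats, which carry no points to detect, and
the two beats inside each stream's delay horizon). The *effective rate* is
the percentage of fully completed complexes among all forecastable
(non-ABEXYOZu) ones. Because the cohort is synthetic, the pipeline also
scores the imputed values against the generator's ground truth:

```r
pts <- setdiff(ICG_COLUMNS, "RR")
cells <- res$imputation$provenance == "imputed"
eval_metrics(res$truth$values[, pts][cells], res$completed_raw$values[, pts][cells])
#>      n          mse       rmse        mae pearson_r     vecv       ccc
#> 1 1516 0.0003934661 0.01983598 0.01470577 0.9927474 98.54982 0.9926882
```

i.e. the forecast landmark times agree with the hidden truth to about 20 ms
RMSE with a concordance of 0.99. Finally, the X-candidate selector compares
each candidate's RR ratio against its reference in typical beats, per
dataset and subtype:

```r
head(res$selection, 3)
#>   dataset_id  subtype  n      sd_x1       sd_x2 chosen
#> 1          S ABEXYOZ3 89 0.03042282 0.008607495     X2
#> 2          S ABEXYOZ2 38 0.03503491 0.017173025     X2
#> 3          S ABEXYOZ1 50 0.02972256 0.015911096     X2
```

X2 is chosen everywhere because this cohort was generated with X2 as the
true X and X1 displaced by a fixed bias in atypical complexes.

Command-line wrappers live under `inst/scripts/`: `simulate.R` writes a
synthetic cohort to an annotations CSV, `run_pipeline.R` runs the workflow
from a YAML config and writes the model (JSON), the completed annotations
(CSV with provenance) and the evaluation report (JSON).

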