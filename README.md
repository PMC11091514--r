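# ortime

Minute-by-minute probabilistic prediction of total anaesthesia time from
streaming intraoperative data, with the evaluation machinery of a silent
prospective deployment: proper scoring against a bias-corrected
scheduled-duration benchmark, stratified accuracy reporting, and
performance-drift monitoring over calendar time.

`ortime` is aimed at perioperative-informatics researchers who want to study
*how* such a real-time predictor behaves — information growth within a case,
ingestion latency, operating-window censoring, drift, retraining policy —
without access to an institutional EHR feed. A discrete-event synthetic
operating-room generator stands in for the feed, so the whole pipeline is
reproducible from a seed.

## The method

For a case at elapsed minute $t$, the model sees only observations whose
*ingestion* time (charting time plus EHR-to-server latency) has passed —
never the future — and outputs a probability histogram over total duration,

$$p_k = \Pr\big(\text{total duration} \in [t + e_k,\ t + e_{k+1})\big),
\qquad k = 1, \dots, K,$$

on $K = 128$ geometric remaining-duration bins. Forecasts are scored with
the continuous ranked probability score,

$$\mathrm{CRPS}(F, y) = \int \big(F(x) - \mathbb{1}\{x \ge y\}\big)^2\,dx
\quad \text{[minutes]},$$

evaluated in closed form for the binned CDF. The benchmark is the
**bias-corrected scheduled duration**: ordinary least squares of actual on
scheduled duration over the training window, $\hat a \cdot \text{scheduled}
+ \hat b$, scored as a point forecast (CRPS = absolute error). Drift is
quantified by regressing the weekly ratio of mean model CRPS to mean
baseline CRPS on week index; a retraining comparison trains a second model
on a more proximal window with the identical spec and compares both on a
later window neither saw.

The predictor itself is a single-hidden-layer feed-forward network over
per-minute summaries of the intraoperative streams (recency of end-of-case
signature tokens — reversal agent, antiemetic, emergence — last flowsheet
values with missingness masks and short-horizon deltas, stream counts,
schedule geometry, hospital/service), trained with a discretized-CRPS loss
by seeded minibatch Adam. See `vignettes/ortime-methods.Rmd` for the full
model account and design rationale.

## Worked example

```r
library(ortime)

cfg <- or_sim_config(n_days = 119, seed = 2024)   # 17 simulated weeks
cap <- or_simulate(cfg)                           # cases + streams + latency + window
cap
#> <or_capture> 3090 / 4257 cases captured (72.6%), 264 downtime hours

cases <- cap$cases
split <- cfg$start_date + 77                      # 11 weeks train, 6 weeks test
cal   <- as.Date(cases$anaesthesia_start, tz = "UTC")
train <- cases[cases$captured & cal < split, ]    # 2011 cases
test  <- cases[cases$captured & cal >= split, ]   # 1079 cases

baseline <- fit_baseline(train)
baseline
#> <sched_baseline> actual = 0.976 * scheduled -2.119  (se 0.004 / 0.648, n = 2011)

vocab <- build_vocab(train, cap$observations[cap$observations$case_id %in% train$case_id, ])
fspec <- build_feature_spec(train, vocab)
feats <- or_features(train, cap$observations, fspec, cap$capture_log)
model <- train_model(feats, duration_model_spec(seed = 1), vocab, fspec)
model
#> <or_duration_model> 47 features -> 32 hidden -> 128 bins on [1, 1440] min
#>   loss crps, 15 epochs on 80000 snapshots; final training loss 9.876

scores <- score_model(model, baseline, test, cap$observations, cap$capture_log)
```

The model roughly halves the benchmark error over ~99 000 held-out
predictions:

```
mean CRPS: model 10.41 min vs baseline 15.65 min (ratio 0.665)
```

The advantage concentrates late in the case (ratio near 1 in the first 5% of
elapsed time, falling steadily as end-of-case signatures arrive), and the
weekly ratio shows no drift on this stationary stream:

```r
drift(scores)
#> <or_drift> 6 weeks; ratio slope -0.00666 per week (95% CI -0.03182 to 0.01849)
#>   weekly CRPS ratio (model/baseline): min 0.632, median 0.654, max 0.727
```

A single live forecast, 30 minutes into one test case:

```r
snap <- replay(test[1, ], cap$observations, t = 30, vocab)
d <- predict(model, snap)
d
#> <duration_distribution> 128 bins on [31.0, 1470.0] min, mean 96.6 min
crps(d, test$actual_duration[1])   # actual duration was 97 min
#> 5.62
```

`run_all(or_run_config(...), out_dir)` chains the whole thing — simulate,
capture, tokenize, fit baseline, train, score, aggregate, drift — and writes
`cases.csv`, `vocab.json`, `model.rds`, `scores.csv`, `aggregates.csv`,
`drift_summary.json` and a digest manifest.

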