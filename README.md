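# vo2quant

Probabilistic estimation of cardiorespiratory fitness (VO2 max, in
ml/kg/min) from free-living wearable data: heart-rate samples and
step-count intervals, plus age, gender and BMI. Instead of a single
number, the model predicts the whole conditional distribution of
VO2 max through a monotone quantile function `Q̂(x, q)`, so users with
rich activity histories get tight intervals and sparse users get
honest, wide ones.

The package is aimed at researchers working on fitness estimation from
consumer devices: it implements the full pipeline — signal
preprocessing, feature engineering, a rearranged quantile
gradient-boosting stack, distributional evaluation metrics, Shapley
attribution — together with a seeded synthetic cohort generator, since
datasets of this kind are proprietary.

## The model in brief

Raw streams are reduced to per-minute triples `(t_i, hr_i, c_i)` (mean
heart rate, cadence from prorated step intervals). From these, a fixed
24-dimensional feature vector is built:

    x = (x_ant, x_chr, x_met, x_resp)

* `x_ant = (age, gender, bmi)`;
* `x_chr`: quartiles of the cadence/heart-rate ratio over activity
  minutes (`c_i > 60` steps/min);
* `x_met`: quartiles of daily MET-minutes, with
  `MET = 6·hr/hr_rest − 5` (floored at 1) and `hr_rest` the day's 10th
  percentile of heart rate between noon and 9 pm;
* `x_resp`: coefficients `(w0, w1, w2)` of continuous two-segment
  piecewise-linear quantile regressions of heart rate on cadence
  (knot fixed at 100 steps/min) at levels 0.1, 0.2, 0.5, 0.8, 0.9 —
  15 numbers describing how the user's heart responds to cadence.

For each level `q = 0.05, …, 0.95` a gradient-boosted learner `f_q` is
trained with the pinball loss
`L_q(y, ŷ) = q·(y−ŷ)₊ + (1−q)·(ŷ−y)₊`. The per-level outputs are
monotonized by rearrangement: `Q̂(x, ·)` is the quantile function of
`f_x(U)`, `U ~ Uniform(0,1)`, where `f_x` interpolates the raw
estimates — computed deterministically by sorting a dense grid.
Evaluation uses CRPS (`2∫ L_q(y, Q̂(x,q)) dq`), the expected
calibration error (mean absolute gap between nominal level and
observed coverage), sharpness (mean predicted interquartile range) and
the median-prediction error. Group-level Shapley values attribute the
median prediction to the four feature groups exactly (all 16
coalitions, interventional coalition values).

## Worked example

```r
library(vo2quant)

# a synthetic cohort: 300 users, 4 observed days each
co   <- generate_cohort(cohort_config(n_users = 300, seed = 42))
mins <- preprocess_streams(co$hr, co$steps)
feat <- extract_features(mins, co$users)

train <- seq_len(200)
stack <- fit_quantile_stack(feature_matrix(feat)[train, ],
                            co$labels$vo2max[train],
                            stack_config(seed = 1))
pred  <- predict_quantiles(stack, feature_matrix(feat)[-train, ])
str(eval_report(pred, co$labels$vo2max[-train]))
```

```
List of 6
 $ ece              : num 0.038
 $ iqr              : num 3.82
 $ crps_mean        : num 2.24
 $ median_error_mean: num -0.114
 $ median_error_sd  : num 3.9
 $ n                : int 100
```

Read: on the 100 held-out users the predicted quantiles deviate from
nominal coverage by about 0.04 on average (calibration), the central
50% interval is about 3.8 ml/kg/min wide (sharpness), and the median
point prediction has an error SD of 3.9 ml/kg/min — close to the
generator's label-noise floor (3.5) and far below the marginal label
SD (≈ 7.5), so the features are doing real work. A single user's
distribution:

```r
round(pred$qhat[1, c("q25", "q50", "q75")], 2)
#   q25   q50   q75
# 32.74 33.62 34.98
```

A command-line interface wraps the same functions
(`exec/vo2quant synth | preprocess | features | train | predict |
evaluate | explain`), reading and writing the CSV dialects documented
in `?read_hr_csv`.

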