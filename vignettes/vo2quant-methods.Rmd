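---
title: "Probabilistic VO2 max estimation from wearable streams: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic VO2 max estimation from wearable streams: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2quant)
```

## The problem

Maximal oxygen uptake (VO2 max, ml of oxygen per kg of body mass per
minute) is the standard measure of cardiorespiratory fitness. Measuring
it properly requires a maximal-effort laboratory test, so consumer
devices estimate it from everyday data instead. `vo2quant` implements a
pipeline that turns two ubiquitous wearable signals — heart-rate samples
and step counts — into a *distributional* estimate of VO2 max: not a
single number but a conditional quantile function
$\hat{Q}(x, q)$, from which a median point estimate, arbitrary
prediction intervals, calibration and sharpness all follow.

Working with predicted distributions matters here because the
information content of free-living data varies enormously between
users: someone who runs daily with a chest strap supports a much
tighter estimate than someone who wears a watch twice a week. A
well-calibrated quantile model makes that difference visible instead of
hiding it behind a point estimate.

## From raw streams to per-minute series

Heart rate arrives as irregular `(timestamp, bpm)` samples; step counts
as intervals `(start, end, steps)`. The pipeline reduces both to a
common per-minute series $(t_i, hr_i, c_i)$:

* $hr_i$ is the arithmetic mean of the samples falling in the minute
  $[t_i, t_i + 1\,\text{min})$; minutes without samples are simply
  absent. Averaging removes the device-dependent sampling frequency.
* $c_i$ (cadence, steps/min) counts the steps attributed to the minute
  window ending at $t_i$. An interval spanning several minute windows
  is prorated proportionally to overlap duration, i.e. under a
  constant-stepping-rate assumption; this conserves total steps for
  any interval layout, which the test suite checks as an invariant.

Two conventions are fixed here and used consistently everywhere:
minute windows are half-open, and every quantile or quartile in the
package uses linear interpolation between closest ranks (type 7 in
`stats::quantile`). Timestamps are interpreted on the user's local
clock, because calendar days and the noon–9pm resting window below are
local-clock concepts.

## Features

The model input is a fixed-order 24-dimensional vector
$x = (x_{ant}, x_{chr}, x_{met}, x_{resp})$.

**Anthropometrics** $x_{ant} = (\text{age}, \text{gender}, \text{bmi})$,
with gender coded female = 0, male = 1 (an arbitrary but fixed coding)
and $\text{bmi} = \text{weight}/\text{height}^2$.

**Cadence to heart-rate ratio** $x_{chr}$: over the *activity minutes*
($c_i > 60$ steps/min) the ratio $c_i/hr_i$ (steps per beat) is a
speed-free proxy of movement economy; its three quartiles form
$x_{chr}$. Fitter users move more steps per heart beat.

**Daily MET-minutes** $x_{met}$: each covered minute gets a metabolic
equivalent estimate $\text{MET} = 6 \cdot hr/hr_{rest} - 5$, where
$hr_{rest}$ is the day's resting heart rate, the 10th percentile of
heart rate between noon and 9 pm (falling back to the whole day when
that window is empty). The estimate is floored at 1: one MET is the
resting metabolic rate, and minutes with $hr < hr_{rest}$ are rest, not
sub-rest. Minutes not covered by data count as one MET; the daily sum
is divided by 1440, so a day without activity scores exactly 1. The
quartiles of the daily values over observed days form $x_{met}$.

**Heart-rate response** $x_{resp}$: over qualifying active moments
($hr_i > 75$ bpm — the MET value 2.5 at the conventional 60 bpm lower
bound of adult resting heart rate — and $c_i > 60$), heart rate is
regressed on cadence with a continuous two-segment piecewise-linear
curve whose knot is fixed at 100 steps/min, the walking-to-running
transition. Quantile regressions at levels 0.1, 0.2, 0.5, 0.8 and 0.9
each yield coefficients $(w0, w1, w2)$ — intercept, slope below the
knot, slope above — for a total of 15 features. The quantile spread
captures heart-rate variability at fixed cadence, not just its center.

Users lacking activity data keep their anthropometrics and get `NA`
sentinels elsewhere; gradient-boosted trees route missing values
natively, so sparse users remain predictable — essential, since the
sharpness analysis below is precisely about such users.

### Fitting the piecewise-linear quantile regressions

Each response fit minimizes the total pinball loss
$\sum_i L_q(hr_i, w0 + w1 \min(c_i, 100) + w2 \max(c_i - 100, 0))$,
$L_q(y, \hat y) = q(y-\hat y)_+ + (1-q)(\hat y - y)_+$. This is a
linear program; the package solves its bounded dual with a hand-written
Mehrotra predictor–corrector interior-point iteration (`rq_ip()`), the
classical Frisch–Newton scheme for quantile regression. Numerical
choices: columns are equilibrated to unit max-magnitude, the duality
gap and residual tolerance is $10^{-9}$ (relative to the response
scale), and coefficients are reported rounded at $10^{-6}$ for
bit-reproducibility. The tests validate the solver against exhaustive
vertex enumeration (an optimal basic solution interpolates three data
points) and against brute-force empirical quantiles in the
intercept-only case.

Degenerate designs are reduced, not rejected: basis columns that are
identically zero or collinear (all cadences on one side of the knot,
too few distinct cadences) are dropped, their coefficients reported as
zero, and the fit flagged. Fits backed by fewer than 30 qualifying
minutes carry a `low_data` flag but still produce coefficients; the
paper-scale deployment must score such users, so refusing to fit would
be the wrong failure mode. Non-crossing of the response curves across
levels is deliberately *not* enforced — levels are fitted
independently, and monotonization belongs to the final prediction
stack, where it is exact.

## The quantile stack and rearrangement

For each level $q = 0.05, 0.10, \ldots, 0.95$ a gradient-boosted tree
ensemble $f_q$ is trained with the pinball objective at that level,
identical hyperparameters and a shared seed. Defaults are the tuned
values of the reference model: depth 4, 313 rounds, bagging fraction
0.75 (frequency 13), learning rate 0.1, minimum 22 samples per leaf,
L1 coefficient 0.142. The backend is xgboost's `reg:quantileerror`
behind a thin adapter; any boosted-tree implementation with a pinball
objective fits the same interface. One mapping caveat: xgboost has no
bagging *frequency* — row subsampling applies every round — so that
configuration field is carried but inert. Training is single-threaded
and therefore bit-reproducible for a fixed seed.

Because the 19 learners are independent, their outputs need not
increase with $q$. The stack is monotonized by **rearrangement**: for a
given $x$, interpolate the pairs $(q_l, f_{q_l}(x))$ piecewise-linearly
into $f_x : [0,1] \to \mathbb{R}$ (clamped constant outside the fitted
levels, since extrapolating tails beyond level 0.05/0.95 has no data
support), and define $\hat{Q}(x, q)$ as the quantile function of
$f_x(U)$, $U \sim \text{Uniform}(0,1)$. Rather than sampling $U$, the
package evaluates $f_x$ on a fixed grid of 1001 equispaced points,
sorts, and reads quantiles off the sorted grid — a deterministic
estimator of the same distributional definition. Sorting makes
monotonicity exact, leaves already-monotone inputs unchanged up to grid
resolution, and (as the classical rearrangement result guarantees, and
the tests check on simulated truths) never increases the distance to
the true conditional quantiles. Rearrangement is applied per prediction
at inference time; training is untouched.

## Evaluation

* **CRPS**. The continuous ranked probability score of the predicted
  CDF $F$ (the inverse of $\hat Q(x,\cdot)$) against a label $y$ is
  computed in quantile space via
  $\text{CRPS} = 2\int_0^1 L_q(y, \hat Q(x,q))\,dq$, a trapezoid sum on
  the rearrangement grid. The identity is verified against direct
  CDF-space quadrature to within 1% in the tests. The score is reported
  positively oriented (lower is better); a point mass at distance $d$
  scores exactly $d$.
* **Calibration (ECE)**. The observed coverage
  $p^{obs}(q) = \tfrac1n \sum_i 1\{y_i \le \hat Q(x_i, q)\}$ is
  compared to the nominal level: the expected calibration error is the
  integral of $|p^{obs}(q) - q|$, approximated by the trapezoid rule
  over the fitted levels $[0.05, 0.95]$. The integrand is unobservable
  beyond the outermost fitted levels without extrapolation, so the
  tails are not integrated; with 19 equispaced levels the difference
  from a full-interval convention is below the resolution of the
  estimates themselves.
* **Sharpness** is the mean predicted interquartile range
  $\hat Q(x, 0.75) - \hat Q(x, 0.25)$; **median error** is the mean and
  sample SD (n−1 denominator) of $y - \hat Q(x, 0.5)$.
* **Cross-validation**: seeded, shuffled, unstratified k-fold CRPS
  (`cv_crps()`), which is also the objective of the pluggable
  grid/random hyperparameter search (`tune_stack()`).

A useful analytic anchor, checked in the tests: the feature-free model
predicting the marginal label quantiles is perfectly calibrated on the
sample that defined it (up to $O(1/n)$), while being maximally
unsharp — calibration alone is a low bar, and both metrics are needed.

## Shapley attribution

The attribution target is the raw median learner $f = f_{0.5}$
(pre-rearrangement). Coalition values are interventional:
$f_S(x)$ is the average of $f$ over background rows with the features
in $S$ pinned to $x$. For the four feature groups the Shapley values
are computed exactly over all $2^4$ coalitions with the factorial
weights; efficiency ($\sum_g \phi_g = f(x) - f_\emptyset(x)$) then
holds to floating-point accuracy, and the tests cross-check the subset
enumeration against an independent permutation-average formulation.
Per-feature values over all 24 features use seeded permutation
sampling with reported standard errors. The background set defaults to
at most 500 training rows drawn with a fixed seed; the full-training
average remains available where exactness matters more than speed.

## The synthetic cohort

Device datasets of this kind are proprietary, so the package ships a
generator that runs the feature model *forward*, making every
statistic the pipeline computes identifiable from the streams it
emits. It makes no claim of physiological realism beyond that
structure; it exists so that the full pipeline — file formats,
preprocessing, features, model, metrics — is exercisable and testable
end to end.

Latent VO2 max is decomposed as

$$\text{vo2} = 36.16 + \Delta_{ant} + v_{int} + v_{slp} + 2.5\, z_{act}$$

* $\Delta_{ant}$: loadings on age (−0.18/year), male gender (+6) and
  BMI (−0.5 per kg/m²), with age and BMI truncated normals matching the
  reference cohort's marginals (40 ± 10 years, 25.5 ± 4.2 kg/m², two
  thirds male);
* $v_{int}, v_{slp}$: two cardiac channels, observed through the
  response curve — the first lowers the intercept $w0^*$ (baseline 95
  bpm, −0.9 bpm per ml/kg/min) and the resting heart rate, the second
  lowers the slopes $w1^*, w2^*$. Splitting the channels keeps the
  ratio features (which mix intercept and slope information at walking
  cadence) from fully absorbing what the response coefficients
  contribute, mirroring the real situation where the response fit
  separates information that summary ratios blur;
* $z_{act}$: an activity latent that scales daily active minutes
  (log-normal, median 40 min/day, between-user log-SD 0.6) and adds
  2.5 ml/kg/min of fitness per SD — the training-volume component.

The channel variances are derived in the constructor so the latent VO2
max has exactly the configured marginal 36.16 ± 6.66 ml/kg/min. Labels
add N(0, 3.5²) noise, the accuracy scale of consumer device estimates,
clamped to the plausible range. Streams follow: rest minutes at
$hr_{rest}$ plus a positive skewed excursion, activity in one-to-three
minute chunks of constant integer cadence (walking ≈ 95, running ≈ 160
steps/min), heart rate on the user's piecewise-linear response with
N(0, 5²) minute noise, samples at irregular sub-minute offsets, and
steps as one multi-minute interval per chunk — which makes uniform
proration exact, so the noiseless configuration round-trips the
generating coefficients to the solver's reporting precision, a
parameter-recovery property the tests rely on.

Every user profile and every (user, day) stream draws from its own
sub-seed, so cohorts are byte-reproducible and insensitive to
generation order.

**What the generator does not emulate**: circadian structure, heart
rate variability, GPS/speed, device-specific artifacts, non-stationary
fitness, or dependence between measurement noise and user behavior.
Consequently, passing the end-to-end tests demonstrates that the
pipeline recovers the structures it assumes when they are present — it
does not validate the model on real populations.

## Scaled-down experiment designs

Two reference experiment designs are reproduced on synthetic cohorts
at desk scale (2000 users, four observed days, ≈ 40 active minutes per
day — against hundreds of observed days per user in the reference
study; sizes chosen as the package's own test conditions):

* **Feature-group ablation** (`ablation_experiment()`): models trained
  with the nested subsets none → $x_{ant}$ → $+x_{chr}$ → $+x_{resp}$
  → $+x_{met}$ are compared on held-out users. On cohorts generated as
  above, the test-set median-error SD decreases along the sequence,
  and the full model lands in the 3–5 ml/kg/min range — between the
  label-noise floor (3.5) and the marginal SD (≈ 7.5) — the scale the
  reference study reports.
* **Sharpness versus available data** (`sharpness_by_activity()`):
  features are recomputed on lookback windows of the users' histories,
  and the mean predicted IQR is reported per bin of available active
  minutes. For this design the model is trained on feature rows pooled
  over lookbacks, emulating deployment where training users carry
  heterogeneous data richness; a model trained only on dense histories
  has never seen a sparse feature pattern and cannot be expected to
  widen on one. Predicted uncertainty then decreases from the
  `<10` active-minute bin to the `>1000` bin.

## Known limitations

* The interior-point solver returns one optimum when the pinball LP
  has a face of solutions (even-sized intercept-only designs); the
  reported coefficients are the solver's canonical interior solution,
  reproducible but not always the classical order statistic.
* ECE at 19 levels is a coarse integral; with small evaluation sets
  its sampling noise dominates the trapezoid error.
* The `bagging_frequency` field is inert under the xgboost backend.
* The generator's couplings are tunable conditions, not estimates of
  physiology; magnitudes were chosen once so the experiment scales are
  comparable to the reference tables, and should not be read as
  ground truth about wearables.
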