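#' Continuous ranked probability score of predicted distributions
#'
#' The CRPS of a predicted CDF `F` against an observation `y` is
#' `integral (F(z) - 1{z >= y})^2 dz`, with `F` recovered as the inverse
#' of the rearranged quantile function. It is computed in quantile space
#' through the identity `CRPS = 2 * integral_0^1 L_q(y, Q(q)) dq`
#' (twice the pinball loss integrated over levels), evaluated by the
#' trapezoid rule on the rearrangement grid. Reported positively
#' oriented: lower is better, 0 is a perfect point mass.
#'
#' @param pred a `vo2_prediction` (see [predict_quantiles()]).
#' @param y observed labels, one per prediction row.
#' @return numeric vector of per-observation CRPS values (ml/kg/min).
#' @export
crps <- function(pred, y) {
  stopifnot(inherits(pred, "vo2_prediction"))
  n <- nrow(pred$grid)
  if (length(y) != n) stop("one label per prediction row is required")
  if (any(apply(pred$grid, 1L, is.unsorted))) {
    stop("non-monotone quantile function")
  }
  u <- pred$grid_levels
  m <- length(u)
  wts <- c(diff(u[1:2]) / 2,
           (u[3:m] - u[1:(m - 2)]) / 2,
           diff(u[(m - 1):m]) / 2)
  res <- matrix(y, n, m) - pred$grid
  U <- matrix(u, n, m, byrow = TRUE)
  L <- U * pmax(res, 0) + (1 - U) * pmax(-res, 0)
  as.vector(2 * (L %*% wts))
}

#' Expected calibration error
#'
#' For each level `q` of the prediction the observed coverage
#' `p_obs(q)` is the fraction of labels at or below the predicted
#' `q`-quantile. The ECE is the integral of `|p_obs(q) - q|` over
#' levels, approximated by the trapezoid rule on the fitted levels
#' (0.05 to 0.95 by default); quantiles beyond the outermost fitted
#' levels are unobservable without extrapolation and the tails are not
#' integrated.
#'
#' @param pred a `vo2_prediction` with one row per labelled user.
#' @param y observed labels.
#' @return a single non-negative number (dimensionless, at most 0.5).
#' @export
ece <- function(pred, y) {
  stopifnot(inherits(pred, "vo2_prediction"))
  if (nrow(pred$qhat) == 0L || length(y) != nrow(pred$qhat)) {
    stop("need a non-empty aligned prediction/label set")
  }
  lv <- pred$levels
  p_obs <- colMeans(matrix(y, nrow(pred$qhat), ncol(pred$qhat)) <= pred$qhat)
  trapz(lv, abs(p_obs - lv))
}

#' Sharpness: mean predicted interquartile range
#'
#' @param pred a `vo2_prediction`.
#' @return mean of `Q(x, 0.75) - Q(x, 0.25)` over rows (ml/kg/min).
#' @export
sharpness <- function(pred) {
  q <- quantile_at(pred, c(0.25, 0.75))
  mean(q[, 2] - q[, 1])
}

#' Error of the median point prediction
#'
#' @param pred a `vo2_prediction`.
#' @param y observed labels.
#' @return list with `mean` and `sd` (sample SD, n-1 denominator) of
#'   `y - Q(x, 0.5)` (ml/kg/min).
#' @export
median_error <- function(pred, y) {
  med <- as.vector(quantile_at(pred, 0.5))
  e <- y - med
  list(mean = mean(e), sd = if (length(e) > 1L) sd(e) else 0)
}

#' Full evaluation report of a prediction set
#'
#' @param pred a `vo2_prediction`.
#' @param y observed labels.
#' @return list with `ece`, `iqr` (sharpness), `crps_mean`,
#'   `median_error_mean`, `median_error_sd` and `n`.
#' @export
eval_report <- function(pred, y) {
  me <- median_error(pred, y)
  list(
    ece = ece(pred, y),
    iqr = sharpness(pred),
    crps_mean = mean(crps(pred, y)),
    median_error_mean = me$mean,
    median_error_sd = me$sd,
    n = length(y)
  )
}

#' Cross-validated CRPS of a stack configuration
#'
#' Seeded, shuffled (unstratified) k-fold split; per fold the stack is
#' fitted on the remaining folds and the mean CRPS measured on the held
#' out fold. This is the objective hyperparameter searches optimize.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param config a [stack_config()].
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @return mean held-out CRPS across folds.
#' @export
cv_crps <- function(x, y, config = stack_config(), k = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k) stop("fewer rows than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    stk <- fit_quantile_stack(x[tr, , drop = FALSE], y[tr], config)
    pr <- predict_quantiles(stk, x[!tr, , drop = FALSE])
    mean(crps(pr, y[!tr]))
  }, numeric(1))
  mean(scores)
}

#' Hyperparameter search over the cross-validated CRPS objective
#'
#' Pluggable random or grid search: each candidate is a partial
#' [stack_config()] override evaluated by [cv_crps()]; the candidate
#' with the lowest cross-validated CRPS wins.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param candidates list of named lists of [stack_config()] overrides.
#' @param k,seed cross-validation settings.
#' @param base a [stack_config()] supplying unspecified fields.
#' @return list with `best_config`, `best_score` and `scores`.
#' @export
tune_stack <- function(x, y, candidates, k = 5L, seed = 1L,
                       base = stack_config()) {
  stopifnot(length(candidates) >= 1L)
  scores <- vapply(candidates, function(ov) {
    cfg <- utils::modifyList(unclass(base), ov)
    cfg <- do.call(stack_config, cfg[setdiff(names(cfg), character())])
    cv_crps(x, y, cfg, k = k, seed = seed)
  }, numeric(1))
  best <- which.min(scores)
  cfg <- do.call(stack_config, utils::modifyList(unclass(base),
                                                 candidates[[best]]))
  list(best_config = cfg, best_score = scores[best], scores = scores)
}

#' Feature-group ablation experiment
#'
#' Re-fits the model with nested subsets of the four feature groups on
#' a train split and evaluates calibration, sharpness, CRPS and
#' median-prediction error on the held-out split. The empty subset is
#' the marginal-quantile baseline.
#'
#' @param features [extract_features()] table (must include all 24
#'   feature columns).
#' @param y labels aligned with `features` rows.
#' @param subsets list of character vectors of group names among
#'   `"ant"`, `"chr"`, `"met"`, `"resp"`; `character(0)` denotes the
#'   feature-free baseline. Default: the nested sequence none, ant,
#'   ant+chr, ant+chr+resp, all.
#' @param config a [stack_config()].
#' @param test_frac held-out fraction of rows.
#' @param seed seed for the split.
#' @return data.frame with one row per subset: `subset`, `ece`, `iqr`,
#'   `crps_mean`, `median_error_mean`, `median_error_sd`, `n_test`.
#' @export
ablation_experiment <- function(features, y,
                                subsets = list(
                                  character(0), "ant", c("ant", "chr"),
                                  c("ant", "chr", "resp"),
                                  c("ant", "chr", "resp", "met")),
                                config = stack_config(),
                                test_frac = 0.3, seed = 1L) {
  groups <- feature_groups()
  n <- nrow(features)
  set.seed(seed)
  test <- sample.int(n) <= round(test_frac * n)
  rows <- lapply(subsets, function(gs) {
    stopifnot(all(gs %in% names(groups)))
    if (length(gs) == 0L) {
      model <- marginal_model(y[!test], levels = config$levels)
      pr <- predict_quantiles(model, features[test, , drop = FALSE])
    } else {
      cols <- unlist(groups[gs], use.names = FALSE)
      xm <- feature_matrix(features, cols)
      model <- fit_quantile_stack(xm[!test, , drop = FALSE], y[!test], config)
      pr <- predict_quantiles(model, xm[test, , drop = FALSE])
    }
    rep <- eval_report(pr, y[test])
    data.frame(
      subset = if (length(gs)) paste(gs, collapse = "+") else "none",
      ece = rep$ece, iqr = rep$iqr, crps_mean = rep$crps_mean,
      median_error_mean = rep$median_error_mean,
      median_error_sd = rep$median_error_sd, n_test = rep$n
    )
  })
  do.call(rbind, rows)
}

#' Sharpness as a function of available activity data
#'
#' Emulates the design of the sharpness-versus-data experiment: user
#' histories are truncated to lookback windows of different lengths,
#' features recomputed per window, predictions made with a fixed
#' trained model, and the mean predicted interquartile range reported
#' per bin of active minutes (minutes with cadence above 60) available
#' in the window.
#'
#' @param model a fitted `quantile_stack`.
#' @param minutes preprocessed minute table ([preprocess_streams()]).
#' @param users user table (see [extract_features()]).
#' @param lookbacks numeric vector of window lengths in days.
#' @param breaks bin edges on active minutes; defaults to the
#'   reference bins 0, 10, 30, 60, 100, 200, 500, 1000, Inf.
#' @return data.frame with `bin`, `n` and mean `iqr` per bin.
#' @export
sharpness_by_activity <- function(model, minutes, users,
                                  lookbacks = c(1, 7, 30, 120, 240),
                                  breaks = c(0, 10, 30, 60, 100, 200,
                                             500, 1000, Inf)) {
  rows <- lapply(lookbacks, function(lb) {
    f <- extract_features(minutes, users, lookback_days = lb)
    pr <- predict_quantiles(model, feature_matrix(f))
    q <- quantile_at(pr, c(0.25, 0.75))
    data.frame(active_minutes = f$active_minutes, iqr = q[, 2] - q[, 1])
  })
  all <- do.call(rbind, rows)
  bin <- cut(all$active_minutes, breaks = breaks, right = FALSE)
  agg <- stats::aggregate(all$iqr, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(bin)[as.character(agg$bin)])
  data.frame(bin = as.character(agg$bin), n = cnt, iqr = agg$x)
}
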