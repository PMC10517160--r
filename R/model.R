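#' Configuration of the gradient-boosted quantile stack
#'
#' Holds the quantile levels and the shared hyperparameters of the
#' per-level learners. The defaults are the tuned values of the
#' reference model (maximal depth 4, 313 estimators, bagging fraction
#' 0.75, bagging frequency 13, learning rate 0.1, minimal samples per
#' leaf 22, L1 regularization 0.142).
#'
#' The backend is xgboost's pinball objective (`reg:quantileerror`).
#' `bagging_fraction` maps to row subsampling, `min_samples_leaf` to the
#' minimal hessian weight per leaf and `l1_reg` to the L1 penalty.
#' `bagging_frequency` is retained for completeness but is inert for
#' this backend, whose row subsampling applies at every boosting round.
#'
#' @param levels strictly increasing quantile levels in (0, 1).
#' @param max_depth maximal tree depth.
#' @param n_estimators number of boosting rounds.
#' @param bagging_fraction row subsampling fraction in (0, 1].
#' @param bagging_frequency subsampling period (kept for configuration
#'   fidelity; see Details).
#' @param learning_rate shrinkage per round.
#' @param min_samples_leaf minimal number of samples in a leaf.
#' @param l1_reg L1 regularization coefficient.
#' @param seed integer seed controlling subsampling.
#' @return object of class `stack_config`.
#' @export
stack_config <- function(levels = seq(0.05, 0.95, by = 0.05),
                         max_depth = 4,
                         n_estimators = 313,
                         bagging_fraction = 0.75,
                         bagging_frequency = 13,
                         learning_rate = 0.1,
                         min_samples_leaf = 22,
                         l1_reg = 0.142,
                         seed = 1L) {
  if (is.unsorted(levels, strictly = TRUE) ||
      any(levels <= 0) || any(levels >= 1)) {
    stop("'levels' must be strictly increasing inside (0, 1)")
  }
  stopifnot(max_depth >= 1, n_estimators >= 1,
            bagging_fraction > 0, bagging_fraction <= 1,
            learning_rate > 0, min_samples_leaf >= 1, l1_reg >= 0)
  structure(
    list(levels = levels, max_depth = as.integer(max_depth),
         n_estimators = as.integer(n_estimators),
         bagging_fraction = bagging_fraction,
         bagging_frequency = as.integer(bagging_frequency),
         learning_rate = learning_rate,
         min_samples_leaf = as.integer(min_samples_leaf),
         l1_reg = l1_reg, seed = as.integer(seed)),
    class = "stack_config"
  )
}

#' @export
print.stack_config <- function(x, ...) {
  cat("Quantile stack configuration\n")
  cat("  levels:", paste(format(x$levels), collapse = " "), "\n")
  cat(sprintf(
    "  depth %d, %d rounds, bagging %.2f (freq %d), lr %.3f, min leaf %d, L1 %.3f, seed %d\n",
    x$max_depth, x$n_estimators, x$bagging_fraction, x$bagging_frequency,
    x$learning_rate, x$min_samples_leaf, x$l1_reg, x$seed))
  invisible(x)
}

.xgb_params <- function(config, q) {
  list(
    objective = "reg:quantileerror",
    quantile_alpha = q,
    max_depth = config$max_depth,
    eta = config$learning_rate,
    subsample = config$bagging_fraction,
    alpha = config$l1_reg,
    min_child_weight = config$min_samples_leaf,
    nthread = 1,
    seed = config$seed
  )
}

#' Fit the stack of gradient-boosted quantile learners
#'
#' Trains one gradient-boosted tree model per quantile level with the
#' pinball objective at that level, all on the same training set and
#' with shared hyperparameters. Missing feature values (`NA`) are routed
#' natively by the trees, so sparse users need not be dropped. Training
#' is deterministic for a fixed seed (single-threaded).
#'
#' @param x numeric feature matrix (or data.frame of the feature
#'   columns); typically [feature_matrix()] output.
#' @param y VO2 max labels (ml/kg/min), between 10 and 90.
#' @param config a [stack_config()].
#' @return object of class `quantile_stack`.
#' @export
fit_quantile_stack <- function(x, y, config = stack_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) < 50L) stop("need at least 50 training rows")
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  if (any(!is.finite(y))) stop("non-finite labels")
  if (any(y < 10 | y > 90)) {
    stop("labels outside the plausible VO2 max range [10, 90] ml/kg/min")
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  boosters <- lapply(config$levels, function(q) {
    xgboost::xgb.train(params = .xgb_params(config, q), data = dtrain,
                       nrounds = config$n_estimators, verbose = 0)
  })
  structure(
    list(levels = config$levels, boosters = boosters, config = config,
         feature_names = colnames(x), n_train = nrow(x)),
    class = "quantile_stack"
  )
}

#' @export
print.quantile_stack <- function(x, ...) {
  cat(sprintf(
    "Quantile stack: %d gradient-boosted learners (q = %.2f ... %.2f), trained on %d rows\n",
    length(x$levels), min(x$levels), max(x$levels), x$n_train))
  invisible(x)
}

#' Marginal-quantile model (no features)
#'
#' The feature-free baseline: for every input it predicts the empirical
#' quantiles of the training labels. On the very sample that defined it,
#' its observed coverage matches the nominal levels, so its expected
#' calibration error is (asymptotically) zero while its sharpness equals
#' the marginal label spread.
#'
#' @param y training labels (ml/kg/min).
#' @param levels quantile levels.
#' @return object of class `marginal_stack`.
#' @export
marginal_model <- function(y, levels = seq(0.05, 0.95, by = 0.05)) {
  structure(
    list(levels = levels, quantiles = quantile7(y, levels),
         n_train = length(y)),
    class = "marginal_stack"
  )
}

#' @export
print.marginal_stack <- function(x, ...) {
  cat(sprintf("Marginal quantile model (%d levels, %d training labels)\n",
              length(x$levels), x$n_train))
  invisible(x)
}

## raw (pre-rearrangement) per-level predictions, n x n_levels
raw_quantiles <- function(object, x) UseMethod("raw_quantiles")

#' @export
raw_quantiles.quantile_stack <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    if (!all(object$feature_names %in% colnames(x))) {
      stop("prediction features do not match training features")
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  d <- xgboost::xgb.DMatrix(x, missing = NA)
  out <- vapply(object$boosters, function(b) predict(b, d),
                numeric(nrow(x)))
  matrix(out, nrow = nrow(x), ncol = length(object$levels))
}

#' @export
raw_quantiles.marginal_stack <- function(object, x) {
  n <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
  matrix(object$quantiles, nrow = n, ncol = length(object$levels),
         byrow = TRUE)
}

#' Monotone rearrangement of raw quantile estimates
#'
#' Independently fitted per-level estimates need not increase with the
#' level. The rearrangement fixes this distributionally: the estimates
#' `(q_l, v_l)` are linearly interpolated into a function `f` on
#' `[0, 1]` (constant beyond the outermost levels), and the monotone
#' estimate is the quantile function of `f(U)` with `U` uniform on
#' `[0, 1]`. That quantile function is computed deterministically by
#' evaluating `f` on a fixed equispaced grid and sorting; rearranged
#' quantiles at requested levels are read off the sorted grid by linear
#' interpolation. Sorting makes monotonicity exact and leaves already
#' monotone inputs unchanged (up to grid resolution).
#'
#' @param values raw estimates: numeric vector of length
#'   `length(levels)`, or a matrix with one row per prediction.
#' @param levels quantile levels of the raw estimates.
#' @param out_levels levels at which rearranged quantiles are wanted.
#' @param grid_size number of equispaced grid points on `[0, 1]`.
#' @return object of class `vo2_prediction`: list with `levels`
#'   (`out_levels`), `qhat` (matrix, rearranged quantiles, one row per
#'   prediction), `raw`, `raw_levels`, `grid` (sorted grid values,
#'   rows are full quantile functions) and `grid_levels`.
#' @examples
#' p <- rearrange_quantiles(c(30, 28, 32), levels = c(0.25, 0.5, 0.75))
#' p$qhat  # non-decreasing
#' @export
rearrange_quantiles <- function(values, levels,
                                out_levels = levels, grid_size = 1001L) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (ncol(values) != length(levels)) {
    stop("'values' and 'levels' lengths differ")
  }
  if (length(levels) < 2L) stop("need at least two levels")
  if (any(!is.finite(values))) stop("non-finite raw quantile values")
  ugrid <- seq(0, 1, length.out = grid_size)
  n <- nrow(values)
  grid <- matrix(0, n, grid_size)
  qhat <- matrix(0, n, length(out_levels))
  for (i in seq_len(n)) {
    f <- approx(levels, values[i, ], xout = ugrid, rule = 2)$y
    s <- sort.int(f, method = "quick")
    grid[i, ] <- s
    qhat[i, ] <- approx(ugrid, s, xout = out_levels)$y
  }
  colnames(qhat) <- sprintf("q%02d", round(100 * out_levels))
  structure(
    list(levels = out_levels, qhat = qhat, raw = values,
         raw_levels = levels, grid = grid, grid_levels = ugrid),
    class = "vo2_prediction"
  )
}

#' @export
print.vo2_prediction <- function(x, ...) {
  cat(sprintf(
    "Rearranged quantile predictions: %d rows at %d levels (%.2f ... %.2f)\n",
    nrow(x$qhat), length(x$levels), min(x$levels), max(x$levels)))
  if (nrow(x$qhat) <= 6) print(round(x$qhat, 3))
  invisible(x)
}

#' Predicted conditional quantiles of VO2 max
#'
#' Evaluates every per-level learner of a stack on the feature rows and
#' monotonizes the results by [rearrange_quantiles()]. The median point
#' prediction is the rearranged 0.5-quantile.
#'
#' @param object a `quantile_stack` or `marginal_stack`.
#' @param x feature matrix (rows are users; a single feature vector is
#'   also accepted).
#' @param out_levels quantile levels to report, default the stack's own.
#' @param grid_size rearrangement grid size.
#' @return a `vo2_prediction` (see [rearrange_quantiles()]).
#' @export
predict_quantiles <- function(object, x, out_levels = object$levels,
                              grid_size = 1001L) {
  if (!inherits(object, c("quantile_stack", "marginal_stack"))) {
    stop("'object' must be a fitted quantile stack")
  }
  if (is.vector(x) && !is.list(x)) x <- matrix(x, nrow = 1L,
                                               dimnames = list(NULL, names(x)))
  raw <- raw_quantiles(object, x)
  rearrange_quantiles(raw, object$levels, out_levels = out_levels,
                      grid_size = grid_size)
}

#' Rearranged quantile at given levels
#'
#' @param pred a `vo2_prediction`.
#' @param q level(s) in `[0, 1]`.
#' @return matrix with one row per prediction and one column per `q`.
#' @export
quantile_at <- function(pred, q) {
  stopifnot(inherits(pred, "vo2_prediction"))
  out <- vapply(seq_len(nrow(pred$grid)), function(i) {
    approx(pred$grid_levels, pred$grid[i, ], xout = q)$y
  }, numeric(length(q)))
  matrix(out, ncol = length(q), byrow = TRUE)
}

#' Save / load a fitted quantile stack
#'
#' The artifact is a directory holding `config.yaml` (the
#' [stack_config()]), one serialized learner per level
#' (`learner_q05.json`, ...), and `manifest.json` recording the seed,
#' training size, feature names and a digest of the training setup.
#'
#' @param stack a `quantile_stack`.
#' @param dir target directory (created if absent).
#' @return `save_stack`: `dir`, invisibly. `load_stack`: the restored
#'   `quantile_stack`.
#' @export
save_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "quantile_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(stack$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  for (i in seq_along(stack$levels)) {
    fn <- file.path(dir, sprintf("learner_q%02d.json",
                                 round(100 * stack$levels[i])))
    xgboost::xgb.save(stack$boosters[[i]], fn)
  }
  manifest <- list(
    package = "vo2quant",
    seed = stack$config$seed,
    n_train = stack$n_train,
    feature_names = stack$feature_names,
    levels = stack$levels
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_stack
#' @export
load_stack <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- stack_config(
    levels = as.numeric(cfg$levels), max_depth = cfg$max_depth,
    n_estimators = cfg$n_estimators,
    bagging_fraction = cfg$bagging_fraction,
    bagging_frequency = cfg$bagging_frequency,
    learning_rate = cfg$learning_rate,
    min_samples_leaf = cfg$min_samples_leaf,
    l1_reg = cfg$l1_reg, seed = cfg$seed
  )
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  boosters <- lapply(config$levels, function(q) {
    xgboost::xgb.load(file.path(dir, sprintf("learner_q%02d.json",
                                             round(100 * q))))
  })
  structure(
    list(levels = config$levels, boosters = boosters, config = config,
         feature_names = manifest$feature_names,
         n_train = manifest$n_train),
    class = "quantile_stack"
  )
}
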