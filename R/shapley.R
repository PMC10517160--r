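#' Median point-prediction function of a stack
#'
#' Shapley attribution explains the median prediction model, i.e. the
#' raw (pre-rearrangement) 0.5-level learner.
#'
#' @param stack a `quantile_stack` (or `marginal_stack`).
#' @return a function mapping a feature matrix to median predictions.
#' @export
median_predictor <- function(stack) {
  if (inherits(stack, "marginal_stack")) {
    med <- approx(stack$levels, stack$quantiles, xout = 0.5, rule = 2)$y
    return(function(x) rep(med, if (is.matrix(x)) nrow(x) else 1L))
  }
  stopifnot(inherits(stack, "quantile_stack"))
  i <- which.min(abs(stack$levels - 0.5))
  if (abs(stack$levels[i] - 0.5) > 1e-8) {
    stop("the stack has no 0.5-level learner")
  }
  booster <- stack$boosters[[i]]
  fnames <- stack$feature_names
  function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (!is.null(fnames) && !is.null(colnames(x))) {
      x <- x[, fnames, drop = FALSE]
    }
    predict(booster, xgboost::xgb.DMatrix(x, missing = NA))
  }
}

#' Value of a feature coalition
#'
#' The interventional coalition value: the average of the model over
#' the background rows with the features in `S` pinned to their values
#' in `x`. The full set gives `f(x)` exactly; the empty set gives the
#' background mean of `f`.
#'
#' @param f model function (matrix in, numeric out), e.g.
#'   [median_predictor()].
#' @param x a single feature vector (named numeric or 1-row matrix).
#' @param S integer or character indices of the features held at `x`.
#' @param background matrix of background feature rows (typically a
#'   training subsample).
#' @return a single number.
#' @export
coalition_value <- function(f, x, S, background) {
  if (is.null(dim(background)) || nrow(background) == 0L) {
    stop("empty background set")
  }
  x <- unlist(x)
  hyb <- background
  if (length(S)) {
    if (is.character(S)) S <- match(S, colnames(background))
    hyb[, S] <- matrix(x[S], nrow(background), length(S), byrow = TRUE)
  }
  mean(f(hyb))
}

#' Exact Shapley values of the four feature groups
#'
#' Treats the groups `(ant, chr, met, resp)` as players and enumerates
#' all 16 coalitions, combining the interventional coalition values
#' with the exact factorial weights
#' `|S|! (m - |S| - 1)! / m!`. Efficiency holds by construction:
#' the four values sum to `f(x)` minus the background mean.
#'
#' @inheritParams coalition_value
#' @param groups named list mapping group names to feature columns
#'   (indices or names); default [feature_groups()].
#' @return named numeric vector of group Shapley values (ml/kg/min),
#'   with attribute `baseline` (the background mean of `f`).
#' @export
shapley_groups <- function(f, x, background, groups = feature_groups()) {
  m <- length(groups)
  idx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, colnames(background)) else g
  })
  nsub <- 2L^m
  # value of every coalition, keyed by bitmask over groups
  v <- numeric(nsub)
  for (mask in 0:(nsub - 1L)) {
    S <- unlist(idx[which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) > 0L)],
                use.names = FALSE)
    v[mask + 1L] <- coalition_value(f, x, S, background)
  }
  fac <- factorial(0:m)
  phi <- numeric(m)
  for (g in seq_len(m)) {
    bit <- bitwShiftL(1L, g - 1L)
    for (mask in 0:(nsub - 1L)) {
      if (bitwAnd(mask, bit) > 0L) next
      ssize <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) > 0L)
      wgt <- fac[ssize + 1L] * fac[m - ssize] / fac[m + 1L]
      phi[g] <- phi[g] + wgt * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
    }
  }
  out <- setNames(phi, names(groups))
  attr(out, "baseline") <- v[1L]
  out
}

#' Monte-Carlo per-feature Shapley values
#'
#' Permutation-sampling estimate of the per-feature Shapley values: for
#' each sampled ordering of the 24 features, features are revealed one
#' by one and the marginal change in the interventional coalition value
#' is credited to the revealed feature. Seeded and reproducible; the
#' standard error of each estimate across permutations is reported.
#'
#' @inheritParams coalition_value
#' @param n_permutations number of sampled feature orderings (>= 100).
#' @param seed integer seed.
#' @return list with `phi` (named numeric, length = n features), `se`
#'   (standard errors) and `baseline`.
#' @export
shapley_features_mc <- function(f, x, background, n_permutations = 200L,
                                seed = 1L) {
  if (n_permutations < 100L) stop("use at least 100 permutations")
  x <- unlist(x)
  p <- length(x)
  B <- nrow(background)
  set.seed(seed)
  contrib <- matrix(0, n_permutations, p)
  for (r in seq_len(n_permutations)) {
    perm <- sample.int(p)
    # stack the p+1 successive hybrids and evaluate f once
    hyb <- background[rep(seq_len(B), p + 1L), , drop = FALSE]
    cur <- background
    for (j in seq_len(p)) {
      cur[, perm[j]] <- x[perm[j]]
      hyb[(j * B + 1L):((j + 1L) * B), ] <- cur
    }
    vals <- f(hyb)
    vS <- vapply(0:p, function(j) mean(vals[(j * B + 1L):((j + 1L) * B)]),
                 numeric(1))
    contrib[r, perm] <- diff(vS)
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, sd) / sqrt(n_permutations)
  list(phi = setNames(phi, names(x)), se = setNames(se, names(x)),
       baseline = coalition_value(f, x, integer(0), background))
}

#' Mean absolute group importance over a dataset
#'
#' Averages `|shapley_groups()|` over the rows of a feature matrix:
#' the group-importance summary of the model.
#'
#' @inheritParams shapley_groups
#' @param X feature matrix, one row per user to attribute.
#' @return data.frame with `group` and `importance`, sorted decreasing.
#' @export
group_importance <- function(f, X, background, groups = feature_groups()) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty dataset")
  absmat <- t(vapply(seq_len(nrow(X)), function(i) {
    abs(shapley_groups(f, X[i, ], background, groups))
  }, numeric(length(groups))))
  imp <- colMeans(absmat)
  out <- data.frame(group = names(groups), importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}
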