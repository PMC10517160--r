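#' Pinball (quantile) loss
#'
#' `L_q(y, yhat) = q * max(y - yhat, 0) + (1 - q) * max(yhat - y, 0)`.
#' This is the loss whose expected minimizer is the q-th quantile; it is
#' the fitting objective of both the heart-rate-on-cadence regressions
#' and the gradient-boosted quantile learners.
#'
#' @param y observed values (numeric vector).
#' @param yhat predicted values, recycled against `y`.
#' @param q quantile level, a single number in (0, 1).
#' @return elementwise losses, a non-negative numeric vector.
#' @examples
#' pinball_loss(10, 6, 0.5)  # 2
#' pinball_loss(6, 10, 0.9)  # 0.4
#' @export
pinball_loss <- function(y, yhat, q) {
  stop_if_not_scalar(q, "q")
  if (q <= 0 || q >= 1) stop("'q' must be strictly inside (0, 1)")
  q * pmax(y - yhat, 0) + (1 - q) * pmax(yhat - y, 0)
}

#' Two-segment piecewise-linear heart-rate-on-cadence model
#'
#' Container for one fitted quantile curve of heart rate against
#' cadence: `hr(c) = w0 + w1 * min(c, knot) + w2 * max(c - knot, 0)`.
#' The curve is continuous at the knot by construction. The knot sits at
#' 100 steps/min by default, the cadence where the walking-to-running
#' transition bends the metabolic response.
#'
#' @param w0 intercept (beats/min).
#' @param w1 slope below the knot (beats/min per step/min).
#' @param w2 slope above the knot.
#' @param knot cadence knot (steps/min).
#' @param q quantile level the curve was fitted at.
#' @param degenerate logical flag: the design did not support all three
#'   basis columns and the fit was reduced (dropped coefficients are 0).
#' @param low_data logical flag: fewer qualifying minutes than the
#'   recommended minimum backed the fit.
#' @return an object of class `pwl_model`.
#' @export
pwl_model <- function(w0, w1, w2, knot = 100, q = 0.5,
                      degenerate = FALSE, low_data = FALSE) {
  structure(
    list(w0 = w0, w1 = w1, w2 = w2, knot = knot, q = q,
         degenerate = degenerate, low_data = low_data),
    class = "pwl_model"
  )
}

#' @export
print.pwl_model <- function(x, ...) {
  cat(sprintf(
    "Piecewise-linear quantile model (q = %.2f, knot = %g steps/min)\n",
    x$q, x$knot))
  cat(sprintf("  w0 = %.4f  w1 = %.4f  w2 = %.4f\n", x$w0, x$w1, x$w2))
  if (x$degenerate) cat("  [degenerate design: reduced basis]\n")
  if (x$low_data) cat("  [low data: fit backed by few qualifying minutes]\n")
  invisible(x)
}

#' Evaluate a piecewise-linear model at given cadences
#'
#' @param object a [pwl_model()].
#' @param cadence numeric vector of cadences (steps/min).
#' @param ... unused.
#' @return predicted heart rate (beats/min).
#' @export
predict.pwl_model <- function(object, cadence, ...) {
  object$w0 + object$w1 * pmin(cadence, object$knot) +
    object$w2 * pmax(cadence - object$knot, 0)
}

## basis of the two-segment curve with a fixed knot
pwl_basis <- function(cadence, knot) {
  cbind(1, pmin(cadence, knot), pmax(cadence - knot, 0))
}

#' Fit one piecewise-linear quantile regression of heart rate on cadence
#'
#' Finds `(w0, w1, w2)` minimizing the total pinball loss at level `q`
#' over the basis `(1, min(c, knot), max(c - knot, 0))`. The
#' minimization is the quantile-regression linear program, solved by a
#' deterministic interior-point method ([rq_ip()]). Coefficients are
#' rounded at 1e-6 for reproducible reporting.
#'
#' Degenerate designs are reduced rather than rejected: a basis column
#' that is constant (all cadences on one side of the knot) or collinear
#' with the intercept is dropped, its coefficient reported as 0 and the
#' model flagged `degenerate`.
#'
#' @param cadence,hr numeric vectors of equal length; the qualifying
#'   minutes (the caller is expected to have applied the activity filter
#'   `hr > 75`, `cadence > 60` where that filter is intended).
#' @param q quantile level in (0, 1).
#' @param knot fixed cadence knot, 100 steps/min by default.
#' @param low_data_min minimum number of points below which the fit is
#'   flagged `low_data` (fitting still proceeds).
#' @return a [pwl_model()].
#' @export
fit_pwl_quantile <- function(cadence, hr, q, knot = 100, low_data_min = 30) {
  stopifnot(length(cadence) == length(hr))
  if (!all(is.finite(cadence)) || !all(is.finite(hr))) {
    stop("non-finite cadence or heart-rate values")
  }
  n <- length(hr)
  if (n < 1L) stop("no points to fit")
  stop_if_not_scalar(q, "q")
  if (q <= 0 || q >= 1) stop("'q' must be strictly inside (0, 1)")

  X <- pwl_basis(cadence, knot)
  keep <- c(TRUE, TRUE, TRUE)
  # column 3 is identically 0 when no cadence exceeds the knot
  if (all(cadence <= knot)) keep[3] <- FALSE
  # column 2 is constant (collinear with intercept) when no cadence is
  # below the knot, or when all cadences coincide
  if (all(cadence >= knot) || length(unique(cadence)) == 1L) keep[2] <- FALSE
  # remaining rank deficiency (e.g. two distinct cadences straddling the
  # knot, or fewer points than columns): drop trailing slope columns
  repeat {
    Xk <- X[, keep, drop = FALSE]
    if (n >= ncol(Xk) && qr(Xk)$rank == ncol(Xk)) break
    keep[max(which(keep[-1])) + 1L] <- FALSE
    if (sum(keep) == 1L) {
      Xk <- X[, 1, drop = FALSE]
      break
    }
  }
  degenerate <- !all(keep)

  fit <- rq_ip(Xk, hr, q)
  w <- numeric(3)
  w[keep] <- fit$coef
  w <- round(w, 6)
  pwl_model(w[1], w[2], w[3], knot = knot, q = q,
            degenerate = degenerate, low_data = n < low_data_min)
}

#' Fit the heart-rate response curves at several quantile levels
#'
#' One independent piecewise-linear quantile regression per level;
#' levels are fitted separately (no non-crossing constraint — the
#' monotonization by rearrangement applies to the final VO2 max
#' prediction stack, not to these response curves).
#'
#' @inheritParams fit_pwl_quantile
#' @param levels strictly increasing quantile levels in (0, 1); the
#'   default `(0.1, 0.2, 0.5, 0.8, 0.9)` gives the 15 response
#'   coefficients used as model features.
#' @return list of [pwl_model()] objects, one per level.
#' @export
fit_hr_response <- function(cadence, hr, levels = c(0.1, 0.2, 0.5, 0.8, 0.9),
                            knot = 100, low_data_min = 30) {
  if (is.unsorted(levels, strictly = TRUE) ||
      any(levels <= 0) || any(levels >= 1)) {
    stop("'levels' must be strictly increasing inside (0, 1)")
  }
  lapply(levels, function(q) {
    fit_pwl_quantile(cadence, hr, q, knot = knot, low_data_min = low_data_min)
  })
}
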