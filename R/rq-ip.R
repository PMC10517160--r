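#' Interior-point solver for the quantile-regression linear program
#'
#' Minimizes the total pinball loss `sum L_q(y_i, X_i b)` over
#' coefficients `b`. The problem is the classical quantile-regression LP
#' (split the residual into positive parts `u`, `v` and minimize
#' `q 1'u + (1-q) 1'v` subject to `X b + u - v = y`); it is solved on its
#' bounded dual `max y'a  s.t.  X'a = (1-q) X'1, 0 <= a <= 1` with a
#' Mehrotra predictor-corrector primal-dual iteration (the Frisch-Newton
#' scheme). The multiplier of the equality constraint is the coefficient
#' vector.
#'
#' @param X numeric design matrix (n x p), full column rank.
#' @param y numeric response vector.
#' @param q quantile level in (0, 1).
#' @param tol convergence tolerance on the duality gap and on primal and
#'   dual residuals.
#' @param maxit maximum number of interior-point iterations.
#' @return list with `coef` (length p), `gap` (final duality gap),
#'   `iters`, and `converged`.
#' @keywords internal
rq_ip <- function(X, y, q, tol = 1e-9, maxit = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n >= p, q > 0, q < 1)

  # equilibrate columns for numerical conditioning; undo at the end
  cscale <- pmax(apply(abs(X), 2L, max), .Machine$double.eps)
  X <- sweep(X, 2L, cscale, "/")

  r <- (1 - q) * colSums(X)
  a <- rep(1 - q, n)          # strictly feasible dual start: X'a = r
  s <- 1 - a
  b <- qr.solve(X, y)         # least-squares warm start for coefficients
  res <- y - as.vector(X %*% b)
  z <- pmax(res, 0) + 1e-4
  w <- pmax(-res, 0) + 1e-4

  amax <- function(x, d) {
    i <- d < -.Machine$double.eps
    if (!any(i)) Inf else min(-x[i] / d[i])
  }

  gap <- Inf
  it <- 0L
  converged <- FALSE
  scale <- 1 + max(abs(y))
  for (it in seq_len(maxit)) {
    rp <- r - as.vector(crossprod(X, a))
    rd <- y - as.vector(X %*% b) + z - w
    gap <- sum(a * z) + sum(s * w)
    if (gap < tol * scale && max(abs(rp)) < tol && max(abs(rd)) < tol * scale) {
      converged <- TRUE
      break
    }
    mu <- gap / (2 * n)
    if (!is.finite(mu) || mu <= 0) break
    Qd <- z / a + w / s
    newton <- function(sig) {
      rc1 <- sig * mu - a * z
      rc2 <- sig * mu - s * w
      rhs2 <- rd + rc1 / a - rc2 / s
      XtQ <- crossprod(X, X / Qd)
      diag(XtQ) <- diag(XtQ) * (1 + 1e-12) + 1e-300
      db <- tryCatch(solve(XtQ, as.vector(crossprod(X, rhs2 / Qd)) - rp),
                     error = function(e) NULL)
      if (is.null(db)) return(NULL)
      da <- (rhs2 - as.vector(X %*% db)) / Qd
      dz <- (rc1 - z * da) / a
      dw <- (rc2 + w * da) / s
      list(da = da, dz = dz, dw = dw, db = db)
    }
    aff <- newton(0)
    if (is.null(aff) ||
        !all(vapply(aff, function(v) all(is.finite(v)), TRUE))) break
    ap <- min(1, 0.9995 * min(amax(a, aff$da), amax(s, -aff$da)))
    ad <- min(1, 0.9995 * min(amax(z, aff$dz), amax(w, aff$dw)))
    mu_aff <- (sum((a + ap * aff$da) * (z + ad * aff$dz)) +
                 sum((s - ap * aff$da) * (w + ad * aff$dw))) / (2 * n)
    sig <- min(1, max(0, (mu_aff / mu)^3))
    dir <- newton(sig)
    if (is.null(dir) ||
        !all(vapply(dir, function(v) all(is.finite(v)), TRUE))) break
    ap <- min(1, 0.9995 * min(amax(a, dir$da), amax(s, -dir$da)))
    ad <- min(1, 0.9995 * min(amax(z, dir$dz), amax(w, dir$dw)))
    a <- a + ap * dir$da
    s <- s - ap * dir$da
    z <- z + ad * dir$dz
    w <- w + ad * dir$dw
    b <- b + ad * dir$db
  }
  list(coef = as.vector(b) / cscale, gap = gap, iters = it,
       converged = converged)
}
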