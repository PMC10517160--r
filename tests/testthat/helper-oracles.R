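# Independent oracles used to validate the implementation. These are
# deliberately naive (enumeration, brute force, Monte Carlo) and kept
# separate from the code paths they check.

# trapezoid rule (local copy: the oracles stay self-contained)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# total pinball loss, written out directly
oracle_pinball_sum <- function(y, yhat, q) {
  r <- y - yhat
  sum(ifelse(r >= 0, q * r, (q - 1) * r))
}

# all data values minimizing the intercept-only pinball objective
oracle_quantile_minimizers <- function(y, q, tol = 1e-9) {
  cand <- sort(unique(y))
  loss <- vapply(cand, function(z) oracle_pinball_sum(y, z, q), numeric(1))
  cand[loss <= min(loss) + tol]
}

# exact piecewise-linear quantile fit by vertex enumeration: an optimal
# basic solution of the LP interpolates p data points
oracle_vertex_fit <- function(cadence, hr, q, knot = 100) {
  X <- cbind(1, pmin(cadence, knot), pmax(cadence - knot, 0))
  n <- length(hr)
  best <- Inf
  best_b <- NULL
  for (cmb in utils::combn(n, 3, simplify = FALSE)) {
    Xi <- X[cmb, , drop = FALSE]
    if (abs(det(Xi)) < 1e-9) next
    b <- solve(Xi, hr[cmb])
    l <- oracle_pinball_sum(hr, as.vector(X %*% b), q)
    if (l < best) {
      best <- l
      best_b <- b
    }
  }
  list(coef = best_b, loss = best)
}

# Monte-Carlo rearrangement: quantile function of f(U), U ~ Uniform(0,1)
oracle_mc_rearrange <- function(levels, values, probs, n = 1e6, seed = 42) {
  set.seed(seed)
  u <- runif(n)
  fu <- approx(levels, values, xout = u, rule = 2)$y
  quantile(fu, probs, type = 7, names = FALSE)
}

# CRPS by direct numerical quadrature of the CDF-space integral,
# with F the inverse of the (piecewise-linear) quantile function
oracle_crps_cdf <- function(grid_levels, grid_values, y, nz = 20000) {
  lo <- min(grid_values, y)
  hi <- max(grid_values, y)
  pad <- 1e-9 + 0.001 * (hi - lo)
  z <- seq(lo - pad, hi + pad, length.out = nz)
  Fz <- approx(grid_values, grid_levels, xout = z, rule = 2,
               ties = "ordered")$y
  Fz[z < min(grid_values)] <- 0
  Fz[z > max(grid_values)] <- 1
  g <- (Fz - as.numeric(z >= y))^2
  sum(diff(z) * (g[-1] + g[-nz])) / 2
}

# Shapley values by averaging marginal contributions over all group
# orderings (independent of the factorial-weight subset enumeration)
oracle_perm_shapley <- function(f, x, background, groups) {
  x <- unlist(x)
  m <- length(groups)
  idx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, colnames(background)) else g
  })
  vhat <- function(S) {
    hyb <- background
    if (length(S)) {
      hyb[, S] <- matrix(x[S], nrow(background), length(S), byrow = TRUE)
    }
    mean(f(hyb))
  }
  perms <- combinat_perms(m)
  phi <- numeric(m)
  for (p in perms) {
    S <- integer(0)
    v_prev <- vhat(S)
    for (g in p) {
      S2 <- c(S, idx[[g]])
      v_new <- vhat(S2)
      phi[g] <- phi[g] + (v_new - v_prev)
      S <- S2
      v_prev <- v_new
    }
  }
  setNames(phi / length(perms), names(groups))
}

combinat_perms <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    for (p in combinat_perms(m - 1L)) {
      rest <- seq_len(m)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# small stream fixture: a user whose heart rate follows a known
# piecewise-linear response exactly
make_pwl_series <- function(n, w0 = 95, w1 = 0.2, w2 = 0.5, knot = 100,
                            cad_range = c(62, 180), noise_sd = 0, seed = 1) {
  set.seed(seed)
  cadence <- sample(seq(cad_range[1], cad_range[2]), n, replace = TRUE)
  hr <- w0 + w1 * pmin(cadence, knot) + w2 * pmax(cadence - knot, 0) +
    rnorm(n, 0, noise_sd)
  data.frame(
    minute = as.POSIXct("2024-03-01 10:00:00", tz = "UTC") + 60 * seq_len(n),
    hr = hr, cadence = cadence
  )
}

# compact synthetic cohort for integration tests
small_cohort <- function(n_users = 80, days = 3, seed = 7, ...) {
  generate_cohort(cohort_config(n_users = n_users, days_per_user = days,
                                seed = seed, ...))
}
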