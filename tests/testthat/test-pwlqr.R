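test_that("pinball loss evaluates the asymmetric check function", {
  expect_equal(pinball_loss(5, 5, 0.3), 0)
  expect_equal(pinball_loss(10, 6, 0.5), 2)
  expect_equal(pinball_loss(6, 10, 0.9), 0.4)
  expect_error(pinball_loss(1, 1, 0), "strictly inside")
  expect_error(pinball_loss(1, 1, 1.2), "strictly inside")
  # vectorized and consistent with the spelled-out form
  set.seed(2)
  y <- rnorm(50); yh <- rnorm(50)
  expect_equal(sum(pinball_loss(y, yh, 0.2)),
               oracle_pinball_sum(y, yh, 0.2))
})

test_that("piecewise-linear prediction uses the fixed-knot basis", {
  m <- pwl_model(95, 0.2, 0.5)
  expect_equal(predict(m, 0), 95)
  expect_equal(predict(m, 100), 115)
  expect_equal(predict(m, 120), 125)
  # continuity at the knot
  eps <- 1e-9
  expect_lt(abs(predict(m, 100 - eps) - predict(m, 100 + eps)), 1e-6)
})

test_that("the fit recovers an exactly piecewise-linear relationship", {
  set.seed(8)
  cad <- sample(61:180, 300, replace = TRUE)
  hr <- 95 + 0.2 * pmin(cad, 100) + 0.5 * pmax(cad - 100, 0)
  for (q in c(0.1, 0.5, 0.9)) {
    m <- fit_pwl_quantile(cad, hr, q)
    expect_equal(c(m$w0, m$w1, m$w2), c(95, 0.2, 0.5), tolerance = 1e-6)
  }
})

test_that("intercept-only fits land on the empirical quantile", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:21, 1)
    y <- round(rnorm(n, 90, 12), 3)
    q <- sample(c(0.1, 0.25, 0.5, 0.75, 0.9), 1)
    m <- fit_pwl_quantile(rep(80, n), y, q)  # constant cadence
    expect_true(m$degenerate)
    expect_equal(m$w1, 0)
    mins <- oracle_quantile_minimizers(y, q)
    # the fitted intercept attains the minimal loss ...
    expect_lte(oracle_pinball_sum(y, m$w0, q),
               oracle_pinball_sum(y, mins[1], q) + 1e-6)
    # ... and lies within the minimizing interval
    expect_gte(m$w0, min(mins) - 1e-6)
    expect_lte(m$w0, max(mins) + 1e-6)
  }
  # at q = 0.5 and odd n the minimizer is the unique sample median
  y <- c(3, 9, 1, 7, 5)
  m <- fit_pwl_quantile(rep(100, 5), y, 0.5)
  expect_equal(m$w0, 5, tolerance = 1e-7)
})

test_that("the solver matches exhaustive vertex enumeration on noisy data", {
  set.seed(17)
  cad <- sample(61:180, 22, replace = TRUE)
  hr <- 95 + 0.2 * pmin(cad, 100) + 0.5 * pmax(cad - 100, 0) + rnorm(22, 0, 6)
  for (q in c(0.2, 0.5, 0.8)) {
    m <- fit_pwl_quantile(cad, hr, q)
    oracle <- oracle_vertex_fit(cad, hr, q)
    got <- oracle_pinball_sum(hr, predict(m, cad), q)
    # the reported coefficients are rounded at 1e-6, which moves the
    # attained loss by at most n * 1e-6 * max basis magnitude
    expect_gte(got, oracle$loss - 1e-9)
    expect_lt(got - oracle$loss, 2e-3)
  }
})

test_that("fitted loss beats random candidate coefficient triples", {
  set.seed(30)
  cad <- sample(61:180, 150, replace = TRUE)
  hr <- 95 + 0.2 * pmin(cad, 100) + 0.5 * pmax(cad - 100, 0) + rnorm(150, 0, 5)
  m <- fit_pwl_quantile(cad, hr, 0.3)
  fit_loss <- oracle_pinball_sum(hr, predict(m, cad), 0.3)
  for (i in 1:200) {
    b <- c(runif(1, 80, 110), runif(1, 0, 0.5), runif(1, 0, 1))
    cand <- b[1] + b[2] * pmin(cad, 100) + b[3] * pmax(cad - 100, 0)
    expect_gte(oracle_pinball_sum(hr, cand, 0.3), fit_loss - 1e-9)
  }
})

test_that("response fits per level are independent and complete", {
  set.seed(4)
  cad <- sample(61:180, 400, replace = TRUE)
  hr <- 95 + 0.2 * pmin(cad, 100) + 0.5 * pmax(cad - 100, 0)
  fits <- fit_hr_response(cad, hr)
  expect_length(fits, 5L)
  coefs <- t(vapply(fits, function(m) c(m$w0, m$w1, m$w2), numeric(3)))
  expect_equal(nrow(coefs) * ncol(coefs), 15L)
  # noiseless data: all levels coincide
  for (i in 2:5) expect_equal(coefs[i, ], coefs[1, ], tolerance = 1e-5)
  one <- fit_hr_response(cad, hr, levels = 0.5)
  expect_length(one, 1L)
  expect_error(fit_hr_response(cad, hr, levels = c(0.5, 0.2)), "increasing")
})

test_that("noisy median fits recover generating coefficients", {
  set.seed(99)
  n <- 5000
  cad <- sample(61:180, n, replace = TRUE)
  b0 <- c(95, 0.2, 0.5)
  hr <- b0[1] + b0[2] * pmin(cad, 100) + b0[3] * pmax(cad - 100, 0) +
    rnorm(n, 0, 5)
  m <- fit_pwl_quantile(cad, hr, 0.5)
  # bootstrap standard errors
  B <- 60
  boot <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    i <- sample.int(n, replace = TRUE)
    mb <- fit_pwl_quantile(cad[i], hr[i], 0.5)
    boot[b, ] <- c(mb$w0, mb$w1, mb$w2)
  }
  se <- apply(boot, 2, sd)
  expect_true(all(abs(c(m$w0, m$w1, m$w2) - b0) <= 3 * se))
})

test_that("degenerate designs reduce to the supported basis columns", {
  set.seed(6)
  # everything below the knot: no second segment
  cad <- sample(61:99, 400, replace = TRUE)
  hr <- 90 + 0.25 * cad + rnorm(400, 0, 2)
  m <- fit_pwl_quantile(cad, hr, 0.5)
  expect_true(m$degenerate)
  expect_equal(m$w2, 0)
  expect_equal(m$w1, 0.25, tolerance = 0.1)
  # two distinct cadences straddling the knot: rank 2
  m2 <- fit_pwl_quantile(rep(c(90, 110), 10), rep(c(100, 120), 10), 0.5)
  expect_true(m2$degenerate)
  # low-data flag below the threshold
  m3 <- fit_pwl_quantile(c(70, 80, 90, 95), c(100, 101, 103, 104), 0.5)
  expect_true(m3$low_data)
})
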