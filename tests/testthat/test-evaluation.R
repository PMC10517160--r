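# build a vo2_prediction from explicit quantile values
pred_from <- function(values, levels = seq(0.05, 0.95, by = 0.05)) {
  rearrange_quantiles(values, levels)
}

test_that("CRPS of point masses and the uniform distribution is analytic", {
  # all quantiles at the label: perfect point mass
  p <- pred_from(rep(40, 19))
  expect_equal(crps(p, 40), 0, tolerance = 1e-9)
  # point mass at distance d scores d
  expect_equal(crps(p, 39), 1, tolerance = 1e-3)
  expect_equal(crps(p, 42.5), 2.5, tolerance = 1e-3)
  # uniform(0, 1) against y = 0.5 scores 1/12 (levels spanning [0, 1]
  # so the interpolated quantile function is the identity)
  lv <- seq(0, 1, length.out = 101)
  pu <- pred_from(lv, levels = lv)
  expect_equal(crps(pu, 0.5), 1 / 12, tolerance = 1e-4)
})

test_that("quantile-space CRPS agrees with the CDF-space integral", {
  set.seed(14)
  for (i in 1:25) {
    mu <- runif(1, 25, 50)
    sdev <- runif(1, 1, 8)
    raw <- qnorm(seq(0.05, 0.95, by = 0.05), mu, sdev) + rnorm(19, 0, 1)
    p <- pred_from(raw)
    y <- rnorm(1, mu, sdev)
    got <- crps(p, y)
    ref <- oracle_crps_cdf(p$grid_levels, p$grid[1, ], y)
    expect_equal(got, ref, tolerance = 0.01 * max(ref, 0.1))
  }
})

test_that("ECE integrates the coverage gap over the fitted levels", {
  lv <- seq(0.05, 0.95, by = 0.05)
  # every label below every predicted quantile: p_obs is identically 1
  p <- pred_from(matrix(rep(seq(30, 48, by = 1), 5), 5, 19, byrow = TRUE))
  y <- rep(10, 5)
  expect_equal(ece(p, y + 10), trapz(lv, abs(1 - lv)), tolerance = 1e-12)
  # n = 1: the coverage curve is a step function
  p1 <- pred_from(seq(30, 48, by = 1))
  e1 <- ece(p1, 35.5)
  step <- as.numeric(35.5 <= p1$qhat[1, ])
  expect_equal(e1, trapz(lv, abs(step - lv)), tolerance = 1e-12)
  expect_error(ece(p1, numeric(0)), "aligned")
})

test_that("the marginal model is calibrated on its own sample", {
  set.seed(10)
  y <- rnorm(4000, 36, 6.6)
  m <- marginal_model(y)
  pr <- predict_quantiles(m, matrix(0, length(y), 1))
  expect_lt(ece(pr, y), 0.02)
  # and its sharpness is the marginal interquartile range
  expect_equal(sharpness(pr),
               diff(quantile(y, c(0.25, 0.75), type = 7, names = FALSE)),
               tolerance = 0.02)
})

test_that("sharpness is the mean predicted interquartile range", {
  p <- pred_from(rep(40, 19))
  expect_equal(sharpness(p), 0, tolerance = 1e-9)
  # two predictions with IQRs 4 and 6
  lv <- seq(0.05, 0.95, by = 0.05)
  v1 <- qunif(lv, 30, 38)   # IQR 4
  v2 <- qunif(lv, 30, 42)   # IQR 6
  p2 <- pred_from(rbind(v1, v2))
  expect_equal(sharpness(p2), 5, tolerance = 1e-6)
  q <- quantile_at(p2, c(0.25, 0.75))
  expect_true(all(q[, 2] - q[, 1] >= 0))
})

test_that("median error reports mean and n-1 standard deviation", {
  lv <- seq(0.05, 0.95, by = 0.05)
  v <- qnorm(lv, 40, 3)
  p <- pred_from(rbind(v, v))
  me <- median_error(p, c(40, 40))
  expect_equal(me$mean, 0, tolerance = 1e-9)
  expect_equal(me$sd, 0, tolerance = 1e-9)
  me2 <- median_error(p, c(39, 41))
  expect_equal(me2$mean, 0, tolerance = 1e-9)
  expect_equal(me2$sd, sqrt(2), tolerance = 1e-9)
  me3 <- median_error(p, c(42, 42))
  expect_equal(me3$mean, 2, tolerance = 1e-9)
})

test_that("metrics are invariant to permuting prediction/label pairs", {
  set.seed(23)
  raw <- matrix(rnorm(40 * 19, 36, 5), 40, 19)
  raw <- t(apply(raw, 1, sort))
  y <- rnorm(40, 36, 6)
  p <- pred_from(raw)
  o <- sample.int(40)
  po <- pred_from(raw[o, ])
  expect_equal(ece(po, y[o]), ece(p, y))
  expect_equal(sharpness(po), sharpness(p))
  expect_equal(mean(crps(po, y[o])), mean(crps(p, y)))
  expect_equal(median_error(po, y[o])$sd, median_error(p, y)$sd)
})

test_that("cross-validated CRPS is seeded and rewards informative features", {
  set.seed(2)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- pmin(pmax(36 + 5 * x[, 1] + rnorm(n, 0, 2), 12), 88)
  cfg <- stack_config(n_estimators = 40, seed = 3)
  s1 <- cv_crps(x, y, cfg, k = 3, seed = 5)
  s2 <- cv_crps(x, y, cfg, k = 3, seed = 5)
  expect_identical(s1, s2)
  x_shuf <- x[sample.int(n), , drop = FALSE]  # break the association
  s_shuf <- cv_crps(x_shuf, y, cfg, k = 3, seed = 5)
  expect_lt(s1, s_shuf)
  expect_error(cv_crps(x[1:2, ], y[1:2], cfg, k = 5), "folds")
})

test_that("the ablation table runs the nested feature subsets", {
  co <- small_cohort(n_users = 150, days = 2, seed = 19)
  mins <- preprocess_streams(co$hr, co$steps)
  f <- extract_features(mins, co$users)
  ab <- ablation_experiment(f, co$labels$vo2max,
                            subsets = list(character(0), "ant",
                                           c("ant", "chr")),
                            config = stack_config(n_estimators = 40, seed = 2),
                            seed = 9)
  expect_equal(ab$subset, c("none", "ant", "ant+chr"))
  expect_true(all(ab$crps_mean > 0))
  expect_true(all(ab$ece >= 0 & ab$ece <= 0.5))
  # the feature-free row is the marginal model: widest predictions
  expect_gt(ab$iqr[1], ab$iqr[3])
})
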