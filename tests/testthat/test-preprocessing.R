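ts <- function(s) as.POSIXct(s, tz = "UTC")

test_that("heart-rate resampling averages within minute windows", {
  # single sample
  out <- resample_hr(data.frame(timestamp = ts("2024-03-01 12:00:30"),
                                bpm = 70))
  expect_equal(out$minute, ts("2024-03-01 12:00:00"))
  expect_equal(out$hr, 70)

  # two samples in one minute
  out <- resample_hr(data.frame(
    timestamp = ts(c("2024-03-01 12:00:10", "2024-03-01 12:00:50")),
    bpm = c(60, 80)))
  expect_equal(out$hr, 70)

  # 90 samples at 1 Hz across two minutes, expected values from a
  # brute-force floor-to-minute grouping
  t0 <- ts("2024-03-01 12:00:00")
  stamps <- t0 + 0:89
  bpm <- c(rep(60, 60), rep(90, 30))
  exp_hr <- tapply(bpm, floor(as.numeric(stamps) / 60), mean)
  out <- resample_hr(data.frame(timestamp = stamps, bpm = bpm))
  expect_equal(out$hr, as.numeric(exp_hr))
  expect_equal(out$minute, t0 + c(0, 60))
})

test_that("resampling rejects bad input and ignores sample order", {
  expect_error(resample_hr(data.frame(timestamp = ts(character(0)),
                                      bpm = numeric(0))), "empty")
  expect_error(resample_hr(data.frame(timestamp = ts("2024-03-01 12:00:00"),
                                      bpm = NaN)), "non-finite")
  expect_error(resample_hr(data.frame(timestamp = ts("2024-03-01 12:00:00"),
                                      bpm = 300)), "range")
  set.seed(3)
  s <- data.frame(timestamp = ts("2024-03-01 08:00:00") + runif(200, 0, 1800),
                  bpm = runif(200, 55, 130))
  a <- resample_hr(s)
  b <- resample_hr(s[sample.int(200), ])
  expect_identical(a, b)
})

test_that("cadence prorates interval steps by minute-window overlap", {
  # interval aligned with a single window
  expect_equal(compute_cadence(data.frame(start = 0, end = 60, steps = 100),
                               minutes = 60), 100)
  # two-minute interval split by the uniform-rate assumption
  expect_equal(compute_cadence(data.frame(start = 0, end = 120, steps = 120),
                               minutes = c(60, 120)), c(60, 60))
  # no intervals at all
  expect_equal(compute_cadence(data.frame(start = numeric(0),
                                          end = numeric(0),
                                          steps = numeric(0)),
                               minutes = c(60, 120)), c(0, 0))
  # misaligned interval: 30 s in each of two windows
  expect_equal(compute_cadence(data.frame(start = 30, end = 90, steps = 80),
                               minutes = c(60, 120)), c(40, 40))
  expect_error(compute_cadence(
    data.frame(start = c(0, 50), end = c(60, 110), steps = c(10, 10)),
    minutes = 60), "overlap")
  expect_error(compute_cadence(data.frame(start = 60, end = 60, steps = 1),
                               minutes = 60), "end")
})

test_that("prorated steps are conserved for arbitrary interval layouts", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    bounds <- sort(runif(2 * k, 0, 3600))
    iv <- data.frame(start = bounds[seq(1, 2 * k, 2)],
                     end = bounds[seq(2, 2 * k, 2)],
                     steps = sample(0:300, k, replace = TRUE))
    minutes <- seq(60, 3720, by = 60)  # covers every interval
    cad <- compute_cadence(iv, minutes)
    expect_equal(sum(cad), sum(iv$steps), tolerance = 1e-9)
    expect_true(all(cad >= 0))
  }
})

test_that("resting heart rate is the 10th percentile of the noon-9pm window", {
  day <- function(hrs, hr) {
    data.frame(minute = ts("2024-03-01 00:00:00") + hrs * 3600, hr = hr)
  }
  expect_equal(resting_hr(day(seq(12, 20, length.out = 30), rep(60, 30))), 60)
  # 11-point set: linear-interpolation percentile lands on the 2nd value
  expect_equal(resting_hr(day(seq(12.1, 20.9, length.out = 11),
                              seq(50, 150, by = 10))), 60)
  # empty window falls back to the whole day
  expect_equal(resting_hr(day(c(7, 8, 9), rep(55, 3))), 55)
  expect_error(resting_hr(day(numeric(0), numeric(0))), "empty")
  # duplicated minutes outside the window do not move the estimate
  base <- day(seq(12.1, 20.9, length.out = 11), seq(50, 150, by = 10))
  padded <- rbind(base, day(c(6, 7, 23), c(40, 40, 40)))
  expect_equal(resting_hr(padded), resting_hr(base))
  # clamped into [30, 120]
  expect_equal(resting_hr(day(13, 125)), 120)
})

test_that("merging requires aligned minutes and zips the streams", {
  hr <- data.frame(minute = ts("2024-03-01 12:00:00"), hr = 80)
  m <- merge_streams(hr, cadence = 80)
  expect_equal(m$cadence, 80)
  expect_equal(m$hr, 80)
  expect_error(merge_streams(hr, cadence = c(1, 2)), "exactly")
  empty <- data.frame(minute = ts(character(0)), hr = numeric(0))
  expect_equal(nrow(merge_streams(empty, numeric(0))), 0L)
})

test_that("resampling then merging a one-sample-per-minute stream is the identity", {
  set.seed(5)
  n <- 120
  t0 <- ts("2024-03-01 08:00:00")
  bpm <- runif(n, 60, 140)
  hr <- data.frame(user_id = "u1", timestamp = t0 + 60 * (0:(n - 1)) + 10,
                   bpm = bpm)
  out <- preprocess_streams(hr, steps = NULL)
  expect_equal(as.numeric(out$minute), as.numeric(t0) + 60 * (0:(n - 1)))
  expect_equal(out$hr, bpm)
  expect_equal(out$cadence, rep(0, n))
})

test_that("cohort-level preprocessing matches the per-user operations", {
  co <- small_cohort(n_users = 5, days = 2, seed = 13)
  mins <- preprocess_streams(co$hr, co$steps)
  u <- co$users$user_id[3]
  hr_u <- co$hr[co$hr$user_id == u, ]
  st_u <- co$steps[co$steps$user_id == u, ]
  rs <- resample_hr(hr_u)
  cad <- compute_cadence(st_u, rs$minute)
  ref <- merge_streams(rs, cad)
  got <- mins[mins$user_id == u, c("minute", "hr", "cadence")]
  rownames(got) <- NULL
  expect_equal(got, ref)
})

test_that("CSV readers enforce headers and drop unparseable rows", {
  td <- withr::local_tempdir()
  co <- small_cohort(n_users = 3, days = 1, seed = 4)
  write_cohort_csv(co, td)
  hr2 <- read_hr_csv(file.path(td, "hr.csv"))
  expect_equal(nrow(hr2), nrow(co$hr))
  expect_lt(max(abs(as.numeric(hr2$timestamp) - as.numeric(co$hr$timestamp))),
            0.01)
  st2 <- read_steps_csv(file.path(td, "steps.csv"))
  expect_equal(st2$steps, co$steps$steps)

  bad <- file.path(td, "bad.csv")
  writeLines(c("user_id,time,bpm", "u1,2024-01-01T00:00:00+0000,70"), bad)
  expect_error(read_hr_csv(bad), "columns")
  writeLines(c("user_id,timestamp,bpm",
               "u1,2024-01-01T10:00:00+0000,70",
               "u1,not-a-time,71"), bad)
  expect_message(out <- read_hr_csv(bad), "dropped 1")
  expect_equal(nrow(out), 1L)
})
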