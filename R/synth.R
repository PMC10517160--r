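## truncated-normal helpers (inverse-CDF sampling: one uniform per draw,
## keeping the per-user RNG stream length fixed)
.tn_draw <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}
.tn_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, var = v)
}

#' Configuration of the synthetic wearable cohort
#'
#' The generator runs the feature model forward: each user has a latent
#' VO2 max decomposed into an anthropometric part (age, gender, BMI
#' loadings), two cardiac channels observed through the heart-rate
#' response curve (one moving its intercept, one its slopes) and an
#' activity channel observed through daily activity volume. Minute
#' streams follow the per-user piecewise-linear heart-rate-on-cadence
#' response with configurable noise; step counts are emitted as
#' multi-minute intervals of constant cadence; labels are the latent
#' VO2 max plus device-style noise.
#'
#' The variances of the two cardiac channels are derived inside the
#' constructor so the latent VO2 max has exactly the configured
#' marginal mean and SD (default 36.16 +/- 6.66 ml/kg/min); the label
#' noise SD defaults to 3.5 ml/kg/min, the accuracy scale of consumer
#' device estimates.
#'
#' @param n_users number of users.
#' @param days_per_user observed days per user.
#' @param seed master seed; every user profile and every (user, day)
#'   stream derives its own sub-seed from it, so cohorts are fully
#'   reproducible and insensitive to generation order.
#' @param vo2_mean,vo2_sd marginal moments of latent VO2 max
#'   (ml/kg/min).
#' @param label_noise_sd SD of the label measurement noise (ml/kg/min).
#' @param p_male probability of a male user (reference cohort is about
#'   two thirds male).
#' @param age_mean,age_sd,age_range truncated-normal age distribution
#'   (years).
#' @param bmi_mean,bmi_sd,bmi_range truncated-normal BMI distribution
#'   (kg/m^2).
#' @param b_age,b_sex,b_bmi loadings of age (per year), male gender and
#'   BMI (per kg/m^2) in latent VO2 max.
#' @param act_coupling ml/kg/min of VO2 max per SD of the activity
#'   latent.
#' @param act_meanlog,act_sdlog_user,act_sdlog_day log-normal activity
#'   volume: median daily active minutes, between-user and between-day
#'   log-SD. The between-user deviation is the activity latent.
#' @param rest_minutes_per_day covered sedentary minutes per day.
#' @param hr_noise_sd SD of minute-level heart-rate noise around the
#'   response curve (bpm).
#' @param hr_sample_jitter_sd SD of within-minute sample jitter (bpm).
#' @param hr_samples_per_minute_max samples per covered minute are
#'   uniform on `1:max` at irregular second offsets.
#' @param hr_rest_mean,hr_rest_coupling,hr_rest_noise_sd,hr_rest_range
#'   resting heart rate: baseline, drop per ml/kg/min of the intercept
#'   channel, noise SD, clamp range (bpm).
#' @param w0_base,w0_coupling,w0_noise_sd response intercept: baseline
#'   (about 95 bpm), drop per ml/kg/min of the intercept channel, and
#'   independent noise.
#' @param w1_base,w1_coupling,w1_noise_sd first-segment slope
#'   (bpm per step/min), coupled to the slope channel.
#' @param w2_base,w2_coupling,w2_noise_sd second-segment slope.
#' @param walk_cadence_mean,walk_cadence_sd,run_cadence_mean,run_cadence_sd
#'   cadence distributions of walking and running chunks (steps/min).
#' @param p_run probability that an activity chunk is running.
#' @param start_date first observed calendar day.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 2000L,
                          days_per_user = 4L,
                          seed = 1L,
                          vo2_mean = 36.16,
                          vo2_sd = 6.66,
                          label_noise_sd = 3.5,
                          p_male = 2 / 3,
                          age_mean = 40, age_sd = 10, age_range = c(18, 75),
                          bmi_mean = 25.5, bmi_sd = 4.2, bmi_range = c(16, 45),
                          b_age = -0.18, b_sex = 6, b_bmi = -0.5,
                          act_coupling = 2.5,
                          act_meanlog = log(40),
                          act_sdlog_user = 0.6,
                          act_sdlog_day = 0.3,
                          rest_minutes_per_day = 120L,
                          hr_noise_sd = 5,
                          hr_sample_jitter_sd = 0.5,
                          hr_samples_per_minute_max = 2L,
                          hr_rest_mean = 62, hr_rest_coupling = 0.4,
                          hr_rest_noise_sd = 3, hr_rest_range = c(45, 85),
                          w0_base = 95, w0_coupling = 0.9, w0_noise_sd = 0.5,
                          w1_base = 0.20, w1_coupling = 0.007,
                          w1_noise_sd = 0.004,
                          w2_base = 0.55, w2_coupling = 0.012,
                          w2_noise_sd = 0.012,
                          walk_cadence_mean = 95, walk_cadence_sd = 8,
                          run_cadence_mean = 160, run_cadence_sd = 8,
                          p_run = 0.15,
                          start_date = as.Date("2024-03-01")) {
  stopifnot(n_users >= 1, days_per_user >= 1, vo2_sd >= 0,
            label_noise_sd >= 0, hr_noise_sd >= 0, act_sdlog_user >= 0)
  age_m <- .tn_moments(age_mean, age_sd, age_range[1], age_range[2])
  bmi_m <- .tn_moments(bmi_mean, bmi_sd, bmi_range[1], bmi_range[2])
  var_ant <- b_age^2 * age_m["var"] + b_sex^2 * p_male * (1 - p_male) +
    b_bmi^2 * bmi_m["var"]
  resid <- vo2_sd^2 - var_ant - act_coupling^2
  if (resid < 0) {
    stop("anthropometric and activity loadings already exceed vo2_sd^2")
  }
  cfg <- list(
    n_users = as.integer(n_users), days_per_user = as.integer(days_per_user),
    seed = as.integer(seed),
    vo2_mean = vo2_mean, vo2_sd = vo2_sd, label_noise_sd = label_noise_sd,
    p_male = p_male,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    b_age = b_age, b_sex = b_sex, b_bmi = b_bmi,
    act_coupling = act_coupling,
    act_meanlog = act_meanlog, act_sdlog_user = act_sdlog_user,
    act_sdlog_day = act_sdlog_day,
    rest_minutes_per_day = as.integer(rest_minutes_per_day),
    hr_noise_sd = hr_noise_sd,
    hr_sample_jitter_sd = hr_sample_jitter_sd,
    hr_samples_per_minute_max = as.integer(hr_samples_per_minute_max),
    hr_rest_mean = hr_rest_mean, hr_rest_coupling = hr_rest_coupling,
    hr_rest_noise_sd = hr_rest_noise_sd, hr_rest_range = hr_rest_range,
    w0_base = w0_base, w0_coupling = w0_coupling, w0_noise_sd = w0_noise_sd,
    w1_base = w1_base, w1_coupling = w1_coupling, w1_noise_sd = w1_noise_sd,
    w2_base = w2_base, w2_coupling = w2_coupling, w2_noise_sd = w2_noise_sd,
    walk_cadence_mean = walk_cadence_mean, walk_cadence_sd = walk_cadence_sd,
    run_cadence_mean = run_cadence_mean, run_cadence_sd = run_cadence_sd,
    p_run = p_run,
    start_date = start_date,
    # derived: analytic centering offsets and cardiac channel SD
    age_mu = unname(age_m["mean"]), bmi_mu = unname(bmi_m["mean"]),
    var_ant = unname(var_ant),
    cardiac_sd = sqrt(unname(resid) / 2)
  )
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d users x %d days, VO2 max %.2f +/- %.2f, label noise %.2f (seed %d)\n",
    x$n_users, x$days_per_user, x$vo2_mean, x$vo2_sd, x$label_noise_sd,
    x$seed))
  invisible(x)
}

#' Draw one synthetic user profile
#'
#' Deterministic in `(config, index)`: anthropometrics, the latent VO2
#' max and its channels, the resting heart rate, the generating
#' response coefficients `(w0*, w1*, w2*)` (higher fitness lowers the
#' intercept and slopes: fitter hearts beat slower at a given cadence),
#' the activity multiplier, and the noisy device-style label.
#'
#' @param config a [cohort_config()].
#' @param index user index in `1:n_users`.
#' @return one-row data.frame of the profile and its latent truth.
#' @export
sample_user <- function(config, index) {
  stopifnot(index >= 1, index <= config$n_users)
  set.seed(sub_seed(config$seed, index))
  male <- rbinom(1, 1, config$p_male)
  age <- .tn_draw(1, config$age_mean, config$age_sd,
                  config$age_range[1], config$age_range[2])
  height <- if (male == 1) rnorm(1, 176, 7) else rnorm(1, 163, 7)
  bmi <- .tn_draw(1, config$bmi_mean, config$bmi_sd,
                  config$bmi_range[1], config$bmi_range[2])
  v_int <- rnorm(1, 0, config$cardiac_sd)
  v_slp <- rnorm(1, 0, config$cardiac_sd)
  z_act <- rnorm(1)
  e_rest <- rnorm(1, 0, config$hr_rest_noise_sd)
  e_w <- rnorm(3)
  e_lab <- rnorm(1, 0, config$label_noise_sd)

  d_ant <- config$b_age * (age - config$age_mu) +
    config$b_sex * (male - config$p_male) +
    config$b_bmi * (bmi - config$bmi_mu)
  c_int <- d_ant + v_int     # cardiac channel seen in the intercept
  c_slp <- d_ant + v_slp     # cardiac channel seen in the slopes
  vo2 <- config$vo2_mean + d_ant + v_int + v_slp + config$act_coupling * z_act
  hr_rest <- min(config$hr_rest_range[2], max(
    config$hr_rest_range[1],
    config$hr_rest_mean - config$hr_rest_coupling * c_int + e_rest))
  w0 <- config$w0_base - config$w0_coupling * c_int +
    config$w0_noise_sd * e_w[1]
  w1 <- max(0.05, config$w1_base - config$w1_coupling * c_slp +
              config$w1_noise_sd * e_w[2])
  w2 <- max(0.15, config$w2_base - config$w2_coupling * c_slp +
              config$w2_noise_sd * e_w[3])
  label <- min(89.5, max(10.5, vo2 + e_lab))
  data.frame(
    user_id = sprintf("u%05d", index), index = as.integer(index),
    age = age, gender = male,
    height_cm = height, weight_kg = bmi * (height / 100)^2,
    vo2max = vo2, label = label,
    hr_rest = hr_rest, w0 = w0, w1 = w1, w2 = w2,
    d_ant = d_ant, v_int = v_int, v_slp = v_slp, z_act = z_act,
    act_mult = exp(config$act_sdlog_user * z_act)
  )
}

#' Simulate one observed day of wearable streams for a user
#'
#' Rest minutes sit at the user's resting heart rate plus a positive
#' skewed excursion with cadence 0; activity comes in chunks of one to
#' three minutes of constant integer cadence (walking or running), the
#' heart rate following the user's piecewise-linear response plus
#' noise. Heart-rate samples are emitted at irregular sub-minute
#' offsets; steps are emitted as one multi-minute interval per chunk
#' (so uniform proration reconstructs the generating cadence exactly).
#'
#' @param user profile row from [sample_user()].
#' @param config a [cohort_config()].
#' @param day_index day number in `1:days_per_user`.
#' @return list with `hr_samples` (timestamp, bpm), `step_intervals`
#'   (start, end, steps) and `truth` (minute, cadence, hr); timestamps
#'   numeric seconds since epoch (UTC).
#' @export
simulate_day <- function(user, config, day_index) {
  sim <- .simulate_day_raw(user, config, day_index)
  list(
    hr_samples = data.frame(timestamp = sim$ts, bpm = sim$bpm),
    step_intervals = if (length(sim$iv_start)) {
      data.frame(start = sim$iv_start, end = sim$iv_end,
                 steps = sim$iv_steps)
    },
    truth = data.frame(minute = sim$minute, cadence = sim$cadence,
                       hr = sim$hr)
  )
}

## hot path: everything as plain vectors, no data.frame allocation
.simulate_day_raw <- function(user, config, day_index) {
  set.seed(sub_seed(sub_seed(config$seed, 709 + day_index), user$index))
  day0 <- as.numeric(as.POSIXct(config$start_date, tz = "UTC")) +
    (day_index - 1) * 86400

  n_act <- round(user$act_mult *
                   exp(rnorm(1, config$act_meanlog, config$act_sdlog_day)))
  n_act <- max(0L, min(600L, n_act))

  a_min <- numeric(0)
  a_cad <- numeric(0)
  iv_start <- iv_end <- iv_steps <- numeric(0)
  if (n_act > 0) {
    lens <- sample(1:3, n_act, replace = TRUE)
    k <- which(cumsum(lens) >= n_act)[1]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (sum(lens) - n_act)
    lens <- lens[lens > 0]
    k <- length(lens)
    run <- runif(k) < config$p_run
    cad <- ifelse(run,
                  pmin(200, pmax(131, round(rnorm(k, config$run_cadence_mean,
                                                  config$run_cadence_sd)))),
                  pmin(130, pmax(62, round(rnorm(k, config$walk_cadence_mean,
                                                 config$walk_cadence_sd)))))
    # lay chunks out with occasional gaps, starting mid-morning
    gaps <- ifelse(runif(k) < 0.1, sample(5:60, k, replace = TRUE), 0)
    gaps[1] <- round(8 * 60 + runif(1) * 6 * 60)
    first <- day0 + 60 * cumsum(gaps + c(0, lens[-k][seq_len(k - 1)]))
    # drop chunks that would sprawl past the end of the calendar day
    ok <- first + 60 * (lens - 1) <= day0 + 86340
    first <- first[ok]
    lens <- lens[ok]
    cad <- cad[ok]
    k <- length(first)
    if (k == 0L) {
      a_min <- a_cad <- numeric(0)
    } else {
    a_min <- rep(first, lens) + 60 * (sequence(lens) - 1)
    a_cad <- cad[rep(seq_len(k), lens)]
    iv_start <- first - 60
    iv_end <- first + 60 * (lens - 1)
    iv_steps <- cad * lens
    }
  }

  rest_pool <- day0 + 60 * (7L * 60L):(23L * 60L - 1L)
  if (length(a_min)) rest_pool <- rest_pool[!(rest_pool %in% a_min)]
  n_rest <- min(config$rest_minutes_per_day, length(rest_pool))
  r_min <- sample(rest_pool, n_rest)
  r_hr <- user$hr_rest + rgamma(n_rest, shape = 1.5, scale = 4)
  a_hr <- if (length(a_min)) {
    user$w0 + user$w1 * pmin(a_cad, 100) + user$w2 * pmax(a_cad - 100, 0) +
      rnorm(length(a_min), 0, config$hr_noise_sd)
  } else numeric(0)

  minute <- c(a_min, r_min)
  cadence <- c(a_cad, rep(0, n_rest))
  hr <- pmin(245, pmax(25, c(a_hr, r_hr)))

  nspm <- sample.int(config$hr_samples_per_minute_max, length(minute),
                     replace = TRUE)
  ridx <- rep.int(seq_along(minute), nspm)
  ts <- minute[ridx] + runif(length(ridx)) * 59.9
  bpm <- hr[ridx]
  if (config$hr_sample_jitter_sd > 0) {
    bpm <- bpm + rnorm(length(ridx), 0, config$hr_sample_jitter_sd)
  }
  bpm <- pmin(249, pmax(21, bpm))
  list(ts = ts, bpm = bpm,
       iv_start = iv_start, iv_end = iv_end, iv_steps = iv_steps,
       minute = minute, cadence = cadence, hr = hr)
}

#' Generate a full synthetic cohort
#'
#' Draws every user profile and every day's streams (all seeded), and
#' assembles the tables the pipeline consumes. Optionally writes the
#' CSV files (`hr.csv`, `steps.csv`, `users.csv`, `labels.csv`) in the
#' dialect the readers expect.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory for the CSV files.
#' @return list of data.frames: `hr` (user_id, timestamp, bpm), `steps`
#'   (user_id, start, end, steps), `users` (user_id, age, gender,
#'   height_cm, weight_kg), `labels` (user_id, vo2max), and `truth`
#'   (per-user latent values including the generating response
#'   coefficients). Timestamp columns are `POSIXct` (UTC).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  nd <- config$days_per_user
  profs <- vector("list", config$n_users)
  hr_l <- vector("list", config$n_users)
  st_l <- vector("list", config$n_users)
  for (i in seq_len(config$n_users)) {
    u <- sample_user(config, i)
    profs[[i]] <- u
    sims <- lapply(seq_len(nd), function(d) .simulate_day_raw(u, config, d))
    hr_l[[i]] <- list(
      user_id = rep(u$user_id, sum(lengths(lapply(sims, `[[`, "ts")))),
      timestamp = unlist(lapply(sims, `[[`, "ts"), use.names = FALSE),
      bpm = unlist(lapply(sims, `[[`, "bpm"), use.names = FALSE)
    )
    ivs <- unlist(lapply(sims, `[[`, "iv_start"), use.names = FALSE)
    if (length(ivs)) {
      st_l[[i]] <- list(
        user_id = rep(u$user_id, length(ivs)),
        start = ivs,
        end = unlist(lapply(sims, `[[`, "iv_end"), use.names = FALSE),
        steps = unlist(lapply(sims, `[[`, "iv_steps"), use.names = FALSE)
      )
    }
  }
  truth <- do.call(rbind, profs)
  hr <- as.data.frame(rbindlist(hr_l))
  steps <- as.data.frame(rbindlist(st_l[!vapply(st_l, is.null, TRUE)]))
  hr$timestamp <- as.POSIXct(hr$timestamp, tz = "UTC", origin = "1970-01-01")
  steps$start <- as.POSIXct(steps$start, tz = "UTC", origin = "1970-01-01")
  steps$end <- as.POSIXct(steps$end, tz = "UTC", origin = "1970-01-01")
  users <- truth[, c("user_id", "age", "gender", "height_cm", "weight_kg")]
  labels <- data.frame(user_id = truth$user_id, vo2max = truth$label)
  cohort <- list(hr = hr, steps = steps, users = users, labels = labels,
                 truth = truth, config = config)
  if (!is.null(out_dir)) write_cohort_csv(cohort, out_dir)
  cohort
}
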