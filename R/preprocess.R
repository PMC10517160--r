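#' Resample irregular heart-rate samples to one-minute means
#'
#' Heart-rate readings arrive at device-dependent, irregular frequency.
#' To remove that dependence the stream is averaged over consecutive
#' one-minute windows: an entry `(t, hr)` is produced for every minute
#' `[t, t + 1 min)` containing at least one sample, with `hr` the
#' arithmetic mean of that minute's readings. Minutes without samples
#' are absent from the output.
#'
#' @param samples data.frame with columns `timestamp` (`POSIXct`, or
#'   numeric seconds) and `bpm` (beats/min, must lie in (20, 250)).
#' @return data.frame with columns `minute` (`POSIXct`, UTC,
#'   minute-aligned, strictly increasing) and `hr`.
#' @examples
#' s <- data.frame(
#'   timestamp = as.POSIXct(c("2024-03-01 12:00:10", "2024-03-01 12:00:50"),
#'                          tz = "UTC"),
#'   bpm = c(60, 80))
#' resample_hr(s)  # one minute at 12:00 with hr = 70
#' @export
resample_hr <- function(samples) {
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("empty heart-rate sample set")
  }
  if (!all(c("timestamp", "bpm") %in% names(samples))) {
    stop("'samples' needs columns 'timestamp' and 'bpm'")
  }
  bpm <- as.numeric(samples$bpm)
  if (any(!is.finite(bpm))) stop("non-finite bpm values")
  if (any(bpm <= 20 | bpm >= 250)) {
    stop("bpm values outside the physiological range (20, 250)")
  }
  tnum <- as.numeric(samples$timestamp)
  if (any(!is.finite(tnum))) stop("non-finite timestamps")
  dt <- data.table(minute = floor(tnum / 60) * 60, bpm = bpm)
  out <- dt[, .(hr = mean(bpm)), keyby = minute]
  data.frame(
    minute = as.POSIXct(out$minute, tz = "UTC", origin = "1970-01-01"),
    hr = out$hr
  )
}

## expand step intervals to prorated steps per minute window (t-60, t];
## intervals: data.table with numeric start, end, steps (+ optional id
## columns carried through by `by_cols`)
.prorate_steps <- function(intervals, by_cols = character()) {
  iv <- as.data.table(intervals)
  iv[, rate := steps / (end - start)]
  iv[, t_first := 60 * (floor(start / 60) + 1)]
  iv[, t_last := 60 * ceiling(end / 60)]
  idx <- rep(seq_len(nrow(iv)), (iv$t_last - iv$t_first) / 60 + 1)
  ex <- iv[idx]
  ex[, minute := t_first + 60 * (seq_len(.N) - 1L), by = idx]
  # overlap of the interval with the half-open minute window (t-60, t]
  ex[, ov := pmax(0, pmin(end, minute) - pmax(start, minute - 60))]
  ex[, .(steps = sum(rate * ov)), keyby = c(by_cols, "minute")]
}

#' Per-minute cadence from step-count intervals
#'
#' Step counts are reported as intervals `(start, end, steps)` of
#' varying length. The cadence at minute `t` counts the steps that fall
#' in the one-minute window ending at `t`, i.e. `(t - 1 min, t]`. Steps
#' of an interval spanning several minute windows are prorated
#' proportionally to overlap duration (constant stepping rate within an
#' interval). Minutes touched by no interval get cadence 0.
#'
#' @param intervals data.frame with columns `start`, `end` (`POSIXct` or
#'   numeric seconds, `end > start`, non-overlapping) and `steps`
#'   (non-negative counts). May have zero rows.
#' @param minutes vector of minute-aligned instants (`POSIXct` or
#'   numeric) at which cadence is wanted.
#' @return numeric vector of cadences (steps/min) aligned with
#'   `minutes`.
#' @examples
#' iv <- data.frame(start = 0, end = 120, steps = 120)
#' compute_cadence(iv, minutes = c(60, 120))  # 60, 60
#' @export
compute_cadence <- function(intervals, minutes) {
  mnum <- as.numeric(minutes)
  if (length(mnum) == 0L) return(numeric(0))
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(0, length(mnum)))
  }
  if (!all(c("start", "end", "steps") %in% names(intervals))) {
    stop("'intervals' needs columns 'start', 'end' and 'steps'")
  }
  iv <- data.table(
    start = as.numeric(intervals$start),
    end = as.numeric(intervals$end),
    steps = as.numeric(intervals$steps)
  )
  if (any(!is.finite(iv$start)) || any(!is.finite(iv$end)) ||
      any(!is.finite(iv$steps))) {
    stop("non-finite interval fields")
  }
  if (any(iv$end <= iv$start)) stop("step interval with end <= start")
  if (any(iv$steps < 0)) stop("negative step counts")
  setkey(iv, start)
  if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
    stop("overlapping step intervals for one user")
  }
  per_min <- .prorate_steps(iv)
  out <- per_min[J(mnum), on = "minute"]
  ifelse(is.na(out$steps), 0, out$steps)
}

#' Daily resting heart rate
#'
#' The resting heart rate of a calendar day is the 10th percentile
#' (linear interpolation between closest ranks) of the per-minute heart
#' rate recorded between noon and 9 pm local time. If the day has no
#' minutes in that window, the 10th percentile over the whole day is
#' used as a fallback. The result is clamped into the physiological
#' range `[30, 120]` beats/min.
#'
#' @param day_series data.frame with columns `minute` (`POSIXct`, one
#'   calendar day, interpreted on the local clock) and `hr`.
#' @return resting heart rate, a single number (beats/min).
#' @export
resting_hr <- function(day_series) {
  if (is.null(day_series) || nrow(day_series) == 0L) {
    stop("empty day: no heart-rate minutes")
  }
  hrs_of_day <- (as.numeric(day_series$minute) %% 86400) / 3600
  win <- hrs_of_day >= 12 & hrs_of_day < 21
  vals <- if (any(win)) day_series$hr[win] else day_series$hr
  min(120, max(30, quantile7(vals, 0.1)))
}

#' Merge a resampled heart-rate series with per-minute cadence
#'
#' @param hr_series data.frame from [resample_hr()] (`minute`, `hr`).
#' @param cadence numeric cadence vector computed at exactly the minutes
#'   of `hr_series` (see [compute_cadence()]).
#' @return data.frame with columns `minute`, `hr`, `cadence`.
#' @export
merge_streams <- function(hr_series, cadence) {
  if (nrow(hr_series) != length(cadence)) {
    stop("cadence must be computed at exactly the heart-rate minutes")
  }
  if (any(!is.finite(cadence)) || any(cadence < 0)) {
    stop("cadence must be finite and non-negative")
  }
  data.frame(minute = hr_series$minute, hr = hr_series$hr, cadence = cadence)
}

#' Preprocess raw streams of a whole cohort into per-minute series
#'
#' Applies [resample_hr()] and [compute_cadence()] per user and merges
#' the results: the canonical `(t, hr, cadence)` representation all
#' features are computed from.
#'
#' @param hr data.frame with columns `user_id`, `timestamp`, `bpm`.
#' @param steps data.frame with columns `user_id`, `start`, `end`,
#'   `steps`; may be empty.
#' @return data.frame with columns `user_id`, `minute` (`POSIXct`, UTC),
#'   `hr`, `cadence`, ordered by user and minute.
#' @export
preprocess_streams <- function(hr, steps) {
  if (is.null(hr) || nrow(hr) == 0L) stop("empty heart-rate stream")
  bpm <- as.numeric(hr$bpm)
  if (any(!is.finite(bpm))) stop("non-finite bpm values")
  if (any(bpm <= 20 | bpm >= 250)) {
    stop("bpm values outside the physiological range (20, 250)")
  }
  hd <- data.table(
    user_id = hr$user_id,
    minute = floor(as.numeric(hr$timestamp) / 60) * 60,
    bpm = bpm
  )
  mins <- hd[, .(hr = mean(bpm)), keyby = .(user_id, minute)]

  if (!is.null(steps) && nrow(steps) > 0L) {
    sv <- data.table(
      user_id = steps$user_id,
      start = as.numeric(steps$start),
      end = as.numeric(steps$end),
      steps = as.numeric(steps$steps)
    )
    if (any(sv$end <= sv$start)) stop("step interval with end <= start")
    if (any(sv$steps < 0)) stop("negative step counts")
    setkey(sv, user_id, start)
    bad <- sv[, if (.N > 1L) any(start[-1] < end[-.N]) else FALSE,
              by = user_id]$V1
    if (any(bad)) stop("overlapping step intervals for one user")
    per_min <- .prorate_steps(sv, by_cols = "user_id")
    mins <- per_min[mins, on = c("user_id", "minute")]
    mins[, cadence := ifelse(is.na(steps), 0, steps)]
    mins[, steps := NULL]
  } else {
    mins[, cadence := 0]
  }
  setorder(mins, user_id, minute)
  data.frame(
    user_id = mins$user_id,
    minute = as.POSIXct(mins$minute, tz = "UTC", origin = "1970-01-01"),
    hr = mins$hr,
    cadence = mins$cadence
  )
}
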