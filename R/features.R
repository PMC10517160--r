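#' Feature layout of the VO2 max model
#'
#' The model input is a 24-dimensional vector concatenating four groups
#' in fixed order: anthropometrics `(age, gender, bmi)`, cadence to
#' heart-rate ratio quartiles `(chr25, chr50, chr75)`, daily MET-minute
#' quartiles `(met25, met50, met75)` and the 15 heart-rate response
#' coefficients `(w0_10, w1_10, w2_10, ..., w0_90, w1_90, w2_90)`.
#'
#' @return `feature_names()`: character vector of the 24 column names.
#' @export
feature_names <- function() {
  resp <- as.vector(t(outer(
    c(10, 20, 50, 80, 90),
    c("w0", "w1", "w2"),
    function(l, w) paste0(w, "_", l)
  )))
  c("age", "gender", "bmi",
    "chr25", "chr50", "chr75",
    "met25", "met50", "met75",
    resp)
}

#' @rdname feature_names
#' @return `feature_groups()`: named list mapping the four group names
#'   (`ant`, `chr`, `met`, `resp`) to their feature names.
#' @export
feature_groups <- function() {
  fn <- feature_names()
  list(ant = fn[1:3], chr = fn[4:6], met = fn[7:9], resp = fn[10:24])
}

#' Anthropometric features
#'
#' `(age, gender, bmi)` with gender coded female = 0, male = 1 and
#' `bmi = weight / height^2` (kg/m^2, height in metres).
#'
#' @param age age in years (must lie in (10, 100)).
#' @param gender `"female"`/`"f"`/`0` or `"male"`/`"m"`/`1`.
#' @param height_cm standing height in centimetres.
#' @param weight_kg body mass in kilograms.
#' @return named numeric vector `(age, gender, bmi)`.
#' @examples
#' anthro_feature(33, "f", 170.9, 67.9)  # bmi 23.24...
#' @export
anthro_feature <- function(age, gender, height_cm, weight_kg) {
  stop_if_not_scalar(age, "age")
  if (age <= 10 || age >= 100) stop("'age' outside (10, 100)")
  g <- if (is.numeric(gender)) {
    as.numeric(gender)
  } else {
    switch(tolower(as.character(gender)),
           "f" = 0, "female" = 0, "m" = 1, "male" = 1,
           stop("unrecognized gender code"))
  }
  if (!g %in% c(0, 1)) stop("gender must code to 0 (female) or 1 (male)")
  stop_if_not_scalar(height_cm, "height_cm")
  stop_if_not_scalar(weight_kg, "weight_kg")
  bmi <- weight_kg / (height_cm / 100)^2
  if (bmi <= 10 || bmi >= 60) stop("computed bmi outside (10, 60)")
  c(age = age, gender = g, bmi = bmi)
}

#' Cadence to heart-rate ratio quartiles
#'
#' Over the activity minutes of a series (cadence above 60 steps/min),
#' the ratio `cadence / hr` (steps per beat) is collected and its three
#' quartiles returned. A user with no activity minutes yields `NA`
#' quartiles (missing-feature sentinel passed through to the tree
#' model).
#'
#' @param series data.frame with columns `hr` and `cadence` (a
#'   per-minute series, see [preprocess_streams()]).
#' @return named numeric vector `(chr25, chr50, chr75)`, possibly `NA`.
#' @export
chr_feature <- function(series) {
  act <- series$cadence > 60
  if (!any(act)) {
    return(c(chr25 = NA_real_, chr50 = NA_real_, chr75 = NA_real_))
  }
  r <- series$cadence[act] / series$hr[act]
  setNames(quantile7(r, c(0.25, 0.5, 0.75)), c("chr25", "chr50", "chr75"))
}

#' Heart-rate-based MET estimate for a minute
#'
#' `MET = 6 * hr / hr_rest - 5`, floored at 1 (one MET is the resting
#' metabolic rate; minutes with heart rate below the resting reference
#' are treated as rest).
#'
#' @param hr heart rate (beats/min), vectorized.
#' @param hr_rest resting heart rate of the day (beats/min, positive).
#' @return MET values (dimensionless, `>= 1`).
#' @examples
#' met_minute(75, 60)  # 2.5
#' @export
met_minute <- function(hr, hr_rest) {
  stop_if_not_scalar(hr_rest, "hr_rest")
  if (hr_rest <= 0) stop("'hr_rest' must be positive")
  pmax(1, 6 * hr / hr_rest - 5)
}

#' Daily MET-minutes ratio
#'
#' MET values of all covered minutes of a day are summed, uncovered
#' minutes contribute one MET each, and the total is divided by 1440
#' (the MET-minutes of a fully resting day). A day without activity
#' therefore scores exactly 1.
#'
#' @param day_series data.frame with column `hr`, the covered minutes of
#'   one calendar day (at most 1440 rows).
#' @param hr_rest resting heart rate of that day (beats/min).
#' @return a single dimensionless number `>= 1`.
#' @export
daily_met <- function(day_series, hr_rest) {
  n <- nrow(day_series)
  if (n == 0L) stop("empty day")
  if (n > 1440L) stop("more covered minutes than a day has")
  (sum(met_minute(day_series$hr, hr_rest)) + (1440 - n)) / 1440
}

#' Quartiles of the daily MET-minute distribution
#'
#' @param daily_values numeric vector of [daily_met()] values, one per
#'   observed day.
#' @return named numeric vector `(met25, met50, met75)`, `NA` when no
#'   day was observed.
#' @export
met_feature <- function(daily_values) {
  if (length(daily_values) == 0L) {
    return(c(met25 = NA_real_, met50 = NA_real_, met75 = NA_real_))
  }
  setNames(quantile7(daily_values, c(0.25, 0.5, 0.75)),
           c("met25", "met50", "met75"))
}

#' Heart-rate response coefficients as a 15-dimensional feature
#'
#' Restricts a per-minute series to qualifying active moments (heart
#' rate above 75 bpm — 2.5 MET at the 60 bpm reference resting rate —
#' and cadence over 60 steps/min), fits one piecewise-linear quantile
#' regression per level with [fit_hr_response()], and flattens the
#' coefficients in the fixed order `(w0, w1, w2)` per level, levels
#' ascending. Without qualifying minutes all 15 entries are `NA`.
#'
#' @inheritParams chr_feature
#' @param levels quantile levels of the response fit.
#' @param knot fixed cadence knot (steps/min).
#' @param low_data_min minimum number of qualifying minutes below which
#'   the `low_data` attribute is set.
#' @return named numeric vector of length 15 (`w0_10 ... w2_90`), with
#'   attributes `low_data` and `degenerate` (logical).
#' @export
response_feature <- function(series, levels = c(0.1, 0.2, 0.5, 0.8, 0.9),
                             knot = 100, low_data_min = 30) {
  nm <- as.vector(t(outer(round(100 * levels), c("w0", "w1", "w2"),
                          function(l, w) paste0(w, "_", l))))
  qual <- series$hr > 75 & series$cadence > 60
  if (!any(qual)) {
    out <- setNames(rep(NA_real_, 3 * length(levels)), nm)
    attr(out, "low_data") <- TRUE
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  fits <- fit_hr_response(series$cadence[qual], series$hr[qual],
                          levels = levels, knot = knot,
                          low_data_min = low_data_min)
  out <- setNames(
    unlist(lapply(fits, function(m) c(m$w0, m$w1, m$w2)), use.names = FALSE),
    nm)
  attr(out, "low_data") <- any(vapply(fits, `[[`, TRUE, "low_data"))
  attr(out, "degenerate") <- any(vapply(fits, `[[`, TRUE, "degenerate"))
  out
}

#' Assemble the 24-dimensional feature vector
#'
#' Concatenates the four groups in the fixed order
#' `(x_ant, x_chr, x_met, x_resp)`. Missing components are `NA`
#' sentinels: the gradient-boosted learners route missing values
#' natively, so users with sparse streams remain predictable.
#'
#' @param ant output of [anthro_feature()].
#' @param chr output of [chr_feature()].
#' @param met output of [met_feature()].
#' @param resp output of [response_feature()].
#' @return named numeric vector of length 24.
#' @export
assemble_features <- function(ant, chr, met, resp) {
  out <- c(ant, chr, met, as.numeric(resp))
  names(out) <- feature_names()
  out
}

## per-user feature computation from an already-preprocessed series
.user_feature_row <- function(series, levels, knot, low_data_min) {
  chr <- chr_feature(series)
  dkey <- floor(as.numeric(series$minute) / 86400)
  mets <- vapply(split(seq_len(nrow(series)), dkey), function(idx) {
    dd <- series[idx, , drop = FALSE]
    daily_met(dd, resting_hr(dd))
  }, numeric(1))
  met <- met_feature(mets)
  resp <- response_feature(series, levels = levels, knot = knot,
                           low_data_min = low_data_min)
  list(chr = chr, met = met, resp = resp)
}

#' Extract model features for every user of a cohort
#'
#' Runs the whole feature stage on a preprocessed minute table: cadence
#' to heart-rate ratio quartiles, daily MET-minute quartiles, heart-rate
#' response coefficients, joined with anthropometrics. Optionally
#' restricts each user's stream to a lookback window ending at their
#' last observed minute, which is how the sharpness-versus-data
#' experiments vary the amount of available history.
#'
#' @param minutes data.frame from [preprocess_streams()] (`user_id`,
#'   `minute`, `hr`, `cadence`).
#' @param users data.frame with columns `user_id`, `age`, `gender`,
#'   `height_cm`, `weight_kg`.
#' @param lookback_days optional window length in days; `NULL` uses all
#'   available history.
#' @param levels,knot,low_data_min response-fit settings, see
#'   [response_feature()].
#' @return data.frame with `user_id`, the 24 feature columns of
#'   [feature_names()], and bookkeeping columns `active_minutes`
#'   (minutes with cadence above 60 in the used window) and `low_data`.
#'   Use [feature_matrix()] to obtain the bare model input.
#' @export
extract_features <- function(minutes, users, lookback_days = NULL,
                             levels = c(0.1, 0.2, 0.5, 0.8, 0.9),
                             knot = 100, low_data_min = 30) {
  stopifnot(all(c("user_id", "minute", "hr", "cadence") %in% names(minutes)))
  stopifnot(all(c("user_id", "age", "gender", "height_cm", "weight_kg")
                %in% names(users)))
  rows <- vector("list", nrow(users))
  mt <- as.data.table(minutes)
  setkey(mt, user_id)
  for (i in seq_len(nrow(users))) {
    u <- users[i, ]
    ant <- anthro_feature(u$age, u$gender, u$height_cm, u$weight_kg)
    su <- mt[J(u$user_id), nomatch = NULL]
    if (!is.null(lookback_days) && nrow(su) > 0L) {
      ref <- max(as.numeric(su$minute))
      su <- su[as.numeric(minute) > ref - lookback_days * 86400]
    }
    if (nrow(su) == 0L) {
      chr <- chr_feature(data.frame(hr = numeric(0), cadence = numeric(0)))
      met <- met_feature(numeric(0))
      resp <- response_feature(
        data.frame(hr = numeric(0), cadence = numeric(0)),
        levels = levels, knot = knot, low_data_min = low_data_min)
      feats <- list(chr = chr, met = met, resp = resp)
      act <- 0L
    } else {
      sdf <- as.data.frame(su)
      feats <- .user_feature_row(sdf, levels, knot, low_data_min)
      act <- sum(sdf$cadence > 60)
    }
    rows[[i]] <- c(
      assemble_features(ant, feats$chr, feats$met, feats$resp),
      active_minutes = act,
      low_data = as.numeric(isTRUE(attr(feats$resp, "low_data")))
    )
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(user_id = users$user_id, out)
}

#' Bare feature matrix from an [extract_features()] table
#'
#' @param features data.frame containing the 24 columns of
#'   [feature_names()] (extra columns are ignored).
#' @param columns feature columns to keep, default all 24.
#' @return numeric matrix with one row per user.
#' @export
feature_matrix <- function(features, columns = feature_names()) {
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  as.matrix(features[, columns, drop = FALSE])
}
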