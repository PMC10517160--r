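## CSV dialects of the pipeline. All timestamps are written as ISO-8601
## with a numeric UTC offset; on reading, clock times are taken at face
## value (day boundaries and the noon-9pm resting window are local-clock
## concepts, so inputs are expected to carry the user's local time).

.ts_fmt <- "%Y-%m-%dT%H:%M:%OS3%z"

.parse_ts <- function(x) {
  x <- as.character(x)
  out <- as.numeric(strptime(x, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    i <- is.na(out)
    if (!any(i)) break
    out[i] <- as.numeric(strptime(x[i], fmt, tz = "UTC"))
  }
  as.POSIXct(out, tz = "UTC", origin = "1970-01-01")
}

.read_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "user_id"))
  if (!identical(names(dt), required)) {
    stop(sprintf("'%s' must have exactly the columns: %s",
                 basename(path), paste(required, collapse = ", ")))
  }
  dt
}

.drop_bad <- function(dt, bad, what, path) {
  if (any(bad)) {
    message(sprintf("%s: dropped %d unparseable %s row(s)",
                    basename(path), sum(bad), what))
    dt <- dt[!bad]
  }
  dt
}

#' Read the pipeline CSV files
#'
#' Strict-header readers for the four input files. Rows whose
#' timestamps or numbers fail to parse are dropped with a logged count.
#'
#' @param path CSV file path.
#' @return data.frame in the layout the pipeline consumes.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
read_hr_csv <- function(path) {
  dt <- .read_strict(path, c("user_id", "timestamp", "bpm"))
  ts <- suppressWarnings(.parse_ts(dt$timestamp))
  bpm <- suppressWarnings(as.numeric(dt$bpm))
  dt[, timestamp := ts][, bpm := bpm]
  dt <- .drop_bad(dt, is.na(ts) | !is.finite(bpm), "heart-rate", path)
  as.data.frame(dt)
}

#' @rdname cohort_io
#' @export
read_steps_csv <- function(path) {
  dt <- .read_strict(path, c("user_id", "start", "end", "steps"))
  s <- suppressWarnings(.parse_ts(dt$start))
  e <- suppressWarnings(.parse_ts(dt$end))
  n <- suppressWarnings(as.numeric(dt$steps))
  dt[, start := s][, end := e][, steps := n]
  dt <- .drop_bad(dt, is.na(s) | is.na(e) | !is.finite(n), "step", path)
  as.data.frame(dt)
}

#' @rdname cohort_io
#' @export
read_users_csv <- function(path) {
  as.data.frame(.read_strict(
    path, c("user_id", "age", "gender", "height_cm", "weight_kg")))
}

#' @rdname cohort_io
#' @export
read_labels_csv <- function(path) {
  as.data.frame(.read_strict(path, c("user_id", "vo2max")))
}

#' Write a generated cohort as the pipeline's CSV files
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hr <- cohort$hr
  hr$timestamp <- format(hr$timestamp, .ts_fmt)
  data.table::fwrite(hr, file.path(dir, "hr.csv"))
  st <- cohort$steps
  st$start <- format(st$start, .ts_fmt)
  st$end <- format(st$end, .ts_fmt)
  data.table::fwrite(st, file.path(dir, "steps.csv"))
  us <- cohort$users
  us$gender <- ifelse(us$gender == 1, "male", "female")
  data.table::fwrite(us, file.path(dir, "users.csv"))
  data.table::fwrite(cohort$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Backs the `vo2quant` executable script: a thin dispatcher over the
#' exported pipeline functions. Subcommands: `synth`, `preprocess`,
#' `features`, `train`, `predict`, `evaluate`, `explain`, `fit-pwlqr`.
#' Arguments are `--key value` pairs; see the README for examples.
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return exit status 0 on success (invisibly).
#' @export
vo2quant_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: vo2quant <synth|preprocess|features|train|predict|",
        "evaluate|explain|fit-pwlqr> [--key value ...]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list()
  kv <- args[-1]
  if (length(kv) %% 2 != 0) stop("arguments must be --key value pairs")
  if (length(kv)) {
    keys <- sub("^--", "", kv[seq(1, length(kv), 2)])
    opt <- as.list(kv[seq(2, length(kv), 2)])
    names(opt) <- keys
  }
  get <- function(k, default = NULL) {
    if (!is.null(opt[[k]])) opt[[k]] else default %||% stop("missing --", k)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  switch(
    cmd,
    synth = {
      cfg <- if (!is.null(opt$config)) {
        do.call(cohort_config, yaml::read_yaml(opt$config))
      } else {
        cohort_config(
          n_users = as.integer(get("users", 100L)),
          days_per_user = as.integer(get("days", 5L)),
          seed = as.integer(get("seed", 1L)))
      }
      generate_cohort(cfg, out_dir = get("out"))
      message("cohort written to ", opt$out)
    },
    preprocess = {
      hr <- read_hr_csv(get("hr"))
      steps <- read_steps_csv(get("steps"))
      mins <- preprocess_streams(hr, steps)
      mins$minute <- format(mins$minute, .ts_fmt)
      data.table::fwrite(mins, get("out"))
    },
    features = {
      mins <- data.table::fread(get("minutes"))
      mins$minute <- .parse_ts(mins$minute)
      users <- read_users_csv(get("users"))
      lb <- opt[["lookback-days"]]
      f <- extract_features(as.data.frame(mins), users,
                            lookback_days = if (!is.null(lb)) as.numeric(lb))
      data.table::fwrite(f, get("out"))
    },
    train = {
      f <- as.data.frame(data.table::fread(get("features")))
      lab <- read_labels_csv(get("labels"))
      stopifnot(identical(f$user_id, lab$user_id))
      cfg <- if (!is.null(opt$config)) {
        do.call(stack_config, yaml::read_yaml(opt$config))
      } else {
        stack_config(seed = as.integer(get("seed", 1L)))
      }
      stk <- fit_quantile_stack(feature_matrix(f), lab$vo2max, cfg)
      save_stack(stk, get("out"))
    },
    predict = {
      stk <- load_stack(get("model"))
      f <- as.data.frame(data.table::fread(get("features")))
      pr <- predict_quantiles(stk, feature_matrix(f))
      out <- data.frame(user_id = f$user_id, pr$qhat,
                        median = as.vector(quantile_at(pr, 0.5)))
      data.table::fwrite(out, get("out"))
    },
    evaluate = {
      stk <- load_stack(get("model"))
      f <- as.data.frame(data.table::fread(get("features")))
      lab <- read_labels_csv(get("labels"))
      stopifnot(identical(f$user_id, lab$user_id))
      pr <- predict_quantiles(stk, feature_matrix(f))
      rep <- eval_report(pr, lab$vo2max)
      jsonlite::write_json(rep, get("out"), auto_unbox = TRUE, digits = NA)
    },
    explain = {
      stk <- load_stack(get("model"))
      f <- as.data.frame(data.table::fread(get("features")))
      X <- feature_matrix(f)
      set.seed(as.integer(get("seed", 1L)))
      bg <- X[sample.int(nrow(X), min(500L, nrow(X))), , drop = FALSE]
      md <- median_predictor(stk)
      phi <- t(vapply(seq_len(nrow(X)), function(i) {
        shapley_groups(md, X[i, ], bg)
      }, numeric(4)))
      out <- data.frame(user_id = f$user_id, phi)
      data.table::fwrite(out, get("out"))
    },
    "fit-pwlqr" = {
      pts <- data.table::fread(get("in"))
      m <- fit_pwl_quantile(pts$cadence, pts$hr,
                            q = as.numeric(get("q", 0.5)))
      cat(jsonlite::toJSON(list(w0 = m$w0, w1 = m$w1, w2 = m$w2),
                           auto_unbox = TRUE, digits = NA), "\n")
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
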