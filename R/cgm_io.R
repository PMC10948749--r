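#' @importFrom stats approx coef confint cor.test lm median pnorm qnorm quantile
#'   rbinom rlnorm rnorm runif sd setNames shapiro.test anova IQR complete.cases
#'   pt qt aggregate as.formula
#' @importFrom utils read.csv write.csv head tail
NULL

SENSOR_RANGE <- c(40, 500)

#' Construct a CGM trace table
#'
#' The in-memory representation used throughout the package is a long
#' data frame of class `cgm_traces`: one row per reading, columns
#' `subject_id`, `cohort` (`"healthy"` or `"prediabetic"`), `timestamp`
#' (POSIXct, timezone-naive local time stored as UTC) and `glucose_mgdl`.
#' Timestamps must be strictly increasing within a subject and glucose must
#' lie in the sensor reporting range 40--500 mg/dL (`NA` marks a missing
#' grid point after resampling).
#'
#' @param subject_id character vector of subject identifiers.
#' @param cohort cohort label(s), `"healthy"` or `"prediabetic"`.
#' @param timestamp POSIXct vector of reading times.
#' @param glucose_mgdl numeric glucose in mg/dL.
#' @return A `cgm_traces` data frame.
#' @export
cgm_traces <- function(subject_id, cohort, timestamp, glucose_mgdl) {
  cohort <- match_cohort(cohort)
  df <- data.frame(
    subject_id = as.character(subject_id),
    cohort = cohort,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    glucose_mgdl = as.numeric(glucose_mgdl),
    stringsAsFactors = FALSE
  )
  validate_traces(df)
  class(df) <- c("cgm_traces", "data.frame")
  attr(df, "origin") <- trace_origin(df)
  df
}

# per-subject sensor-activation date (day 1), kept as an attribute so that
# day indexing survives windowing and regridding
trace_origin <- function(df) {
  d <- as.character(as.Date(df$timestamp, tz = "UTC"))
  vapply(split(d, df$subject_id), min, character(1))
}

match_cohort <- function(cohort) {
  cohort <- as.character(cohort)
  bad <- !cohort %in% c("healthy", "prediabetic")
  if (any(bad)) {
    stop("unknown cohort label(s): ", paste(unique(cohort[bad]), collapse = ", "))
  }
  cohort
}

validate_traces <- function(df) {
  ok <- is.na(df$glucose_mgdl) |
    (df$glucose_mgdl >= SENSOR_RANGE[1] & df$glucose_mgdl <= SENSOR_RANGE[2])
  if (!all(ok)) stop("glucose outside sensor range [40, 500] mg/dL")
  by_subj <- split(df$timestamp, df$subject_id)
  mono <- vapply(by_subj, function(ts) all(diff(as.numeric(ts)) > 0), logical(1))
  if (!all(mono)) {
    stop("timestamps not strictly increasing for subject(s): ",
         paste(names(by_subj)[!mono], collapse = ", "))
  }
  invisible(df)
}

#' @export
print.cgm_traces <- function(x, ...) {
  ns <- length(unique(x$subject_id))
  cat(sprintf("<cgm_traces> %d readings, %d subject(s)\n", nrow(x), ns))
  if (nrow(x)) {
    cat(sprintf("  span: %s to %s\n", format(min(x$timestamp)), format(max(x$timestamp))))
    cat(sprintf("  cohorts: %s\n",
                paste(sprintf("%s=%d", names(table(x$cohort[!duplicated(x$subject_id)])),
                              table(x$cohort[!duplicated(x$subject_id)])), collapse = ", ")))
  }
  invisible(x)
}

#' Read CGM traces from CSV
#'
#' Expects the fixed dialect `subject_id,timestamp,glucose_mgdl` with
#' ISO-8601 timestamps. Rows with unparseable timestamps or glucose outside
#' the sensor range \[40, 500\] mg/dL are dropped; the drop count is reported
#' with a message and attached as attribute `dropped`.
#'
#' @param path path to a trace CSV.
#' @param cohort optional named character vector mapping subject_id to
#'   cohort; unlisted subjects default to `"healthy"`.
#' @return A [cgm_traces] data frame with attribute `dropped` (rows removed).
#' @export
read_trace_csv <- function(path, cohort = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "timestamp", "glucose_mgdl")
  if (!all(need %in% names(raw))) {
    stop("trace CSV must have header 'subject_id,timestamp,glucose_mgdl'")
  }
  ts <- parse_iso_times(raw$timestamp)
  glu <- suppressWarnings(as.numeric(raw$glucose_mgdl))
  keep <- !is.na(ts) & !is.na(glu) &
    glu >= SENSOR_RANGE[1] & glu <= SENSOR_RANGE[2]
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("read_trace_csv: dropped %d invalid row(s) from %s", dropped, path))
  }
  if (!any(keep)) stop("no valid rows in ", path)
  ids <- raw$subject_id[keep]
  co <- if (is.null(cohort)) rep("healthy", length(ids)) else {
    out <- unname(cohort[ids])
    out[is.na(out)] <- "healthy"
    out
  }
  ord <- order(ids, ts[keep])
  tr <- cgm_traces(ids[ord], co[ord], ts[keep][ord], glu[keep][ord])
  attr(tr, "dropped") <- dropped
  tr
}

#' Write CGM traces to CSV
#'
#' Emits the fixed dialect `subject_id,timestamp,glucose_mgdl` (ISO-8601
#' timestamps, UTF-8, LF line endings, '.' decimal separator). Missing grid
#' points are omitted, so write/read round-trips preserve observed readings.
#'
#' @param traces a [cgm_traces] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  df <- traces[!is.na(traces$glucose_mgdl), , drop = FALSE]
  out <- data.frame(
    subject_id = df$subject_id,
    timestamp = format(df$timestamp, "%Y-%m-%dT%H:%M:%S"),
    glucose_mgdl = fmt_num(df$glucose_mgdl),
    stringsAsFactors = FALSE
  )
  write_csv_lf(out, path)
  invisible(path)
}

# lenient ISO-8601 parser: unparseable entries become NA, never an error
parse_iso_times <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in fmts) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  out
}

fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "fg", digits = digits, flag = "#")
  out <- sub("\\.$", "", sub("0+$", "", out))
  out[is.na(x)] <- ""
  trimws(out)
}

write_csv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = ","))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Resample a trace onto a regular grid
#'
#' Places each subject's readings on a regular grid anchored at local
#' midnight of that subject's first reading, linearly interpolating between
#' observations. Grid points farther than `max_gap` minutes from any
#' observation are emitted as missing (`NA`), never interpolated across.
#'
#' @param traces a [cgm_traces] data frame.
#' @param interval grid interval in minutes (default 15, the sensor's
#'   historic-log cadence).
#' @param max_gap maximum distance in minutes from an observation for a grid
#'   point to be interpolated (default 60).
#' @return A gridded [cgm_traces] data frame (attribute `interval_min` set);
#'   missing grid points carry `glucose_mgdl = NA`.
#' @export
resample_to_grid <- function(traces, interval = 15, max_gap = 60) {
  stopifnot(interval > 0)
  if (nrow(traces) == 0) stop("empty trace")
  pieces <- lapply(split(seq_len(nrow(traces)), traces$subject_id), function(idx) {
    sub <- traces[idx, , drop = FALSE]
    obs <- sub[!is.na(sub$glucose_mgdl), , drop = FALSE]
    if (nrow(obs) == 0) return(NULL)
    t0 <- trunc(obs$timestamp[1], units = "days")
    grid <- seq(t0, max(obs$timestamp), by = interval * 60)
    tn <- as.numeric(obs$timestamp)
    gn <- as.numeric(grid)
    val <- approx(tn, obs$glucose_mgdl, xout = gn, method = "linear",
                  rule = 1, ties = "ordered")$y
    # distance from each grid point to the nearest observation
    pos <- findInterval(gn, tn)
    d_left <- ifelse(pos >= 1, gn - tn[pmax(pos, 1)], Inf)
    d_right <- ifelse(pos < length(tn), tn[pmin(pos + 1L, length(tn))] - gn, Inf)
    near <- pmin(d_left, d_right) / 60
    val[near > max_gap] <- NA
    data.frame(subject_id = sub$subject_id[1], cohort = sub$cohort[1],
               timestamp = grid, glucose_mgdl = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cgm_traces", "data.frame")
  attr(out, "interval_min") <- interval
  org <- attr(traces, "origin")
  if (is.null(org) || !all(unique(out$subject_id) %in% names(org))) {
    org <- trace_origin(out)
  }
  attr(out, "origin") <- org
  out
}

#' Restrict traces to the analysis window (days 2--14)
#'
#' Day 1 is the calendar day of each subject's first reading (sensor
#' activation); the first day is discarded to avoid early-wear sensor
#' artefacts, and readings from calendar day 2 through day 14 inclusive are
#' retained.
#'
#' @param traces a [cgm_traces] data frame.
#' @param first_day first retained day index (default 2).
#' @param last_day last retained day index (default 14).
#' @return A [cgm_traces] data frame restricted to the window.
#' @export
analysis_window <- function(traces, first_day = 2, last_day = 14) {
  di <- day_index(traces)
  keep <- di >= first_day & di <= last_day
  if (!any(keep)) stop("empty analysis window: no data on days ",
                       first_day, "-", last_day)
  out <- traces[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cgm_traces", "data.frame")
  attr(out, "interval_min") <- attr(traces, "interval_min")
  org <- attr(traces, "origin")
  attr(out, "origin") <- if (!is.null(org)) org else trace_origin(traces)
  out
}

#' Calendar day index within each subject's trace
#'
#' @param traces a [cgm_traces] data frame.
#' @return Integer vector, day 1 = calendar day of the subject's first
#'   reading (taken from the trace's stored activation date where available,
#'   so windowed traces keep their original day numbering).
#' @export
day_index <- function(traces) {
  date <- as.Date(traces$timestamp, tz = "UTC")
  org <- attr(traces, "origin")
  if (is.null(org) || !all(unique(traces$subject_id) %in% names(org))) {
    org <- vapply(split(as.character(date), traces$subject_id), min, character(1))
  }
  as.integer(date - as.Date(unname(org[traces$subject_id]))) + 1L
}

#' Read or write the per-subject biomarker panel
#'
#' One row per subject with columns `subject_id`, `cohort`, `hba1c`,
#' `ogtt_2h`, `homa_ir`, `hscrp`, `cortisol`, `fbg_baseline`, `fbg_end`.
#'
#' @param path CSV path.
#' @return `read_panel_csv`: a data frame. `write_panel_csv`: `path`, invisibly.
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort", "hba1c", "ogtt_2h", "homa_ir", "hscrp",
            "cortisol", "fbg_baseline", "fbg_end")
  if (!all(need %in% names(df))) {
    stop("panel CSV missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @param panel panel data frame.
#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path) {
  out <- panel
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  write_csv_lf(out, path)
  invisible(path)
}

#' Read or write the per-subject daily activity table
#'
#' Columns `subject_id`, `date`, `steps`, `hr_bpm`, `sleep_min`.
#'
#' @param path CSV path.
#' @return `read_activity_csv`: a data frame. `write_activity_csv`: `path`.
#' @export
read_activity_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "date", "steps", "hr_bpm", "sleep_min")
  if (!all(need %in% names(df))) {
    stop("activity CSV missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @param activity activity data frame.
#' @rdname read_activity_csv
#' @export
write_activity_csv <- function(activity, path) {
  out <- activity
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  write_csv_lf(out, path)
  invisible(path)
}
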