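# Glycemic-variability index engine.
#
# All per-day operations take a numeric vector of glucose readings in mg/dL
# (NA = missing grid point) and return the documented undefined-day marker
# (NA) rather than throwing on degenerate input.

#' Blood-glucose risk transform
#'
#' The logarithmic symmetrizing transform of the blood-glucose scale,
#' `f(BG) = 1.509 * ((ln BG)^1.084 - 5.381)`, maps the clinically asymmetric
#' glucose range onto a symmetric risk space: `f` is monotone increasing with
#' a unique root between 112 and 113 mg/dL. The risk is `r(BG) = 10 f(BG)^2`,
#' split into a low-glucose component `rl` (f < 0) and a high-glucose
#' component `rh` (f > 0); at most one of the two is nonzero at any glucose.
#'
#' @param bg glucose in mg/dL, within the sensor range \[40, 500\].
#' @return `bg_risk`: a list with numeric vectors `rl` and `rh`.
#' @export
bg_risk <- function(bg) {
  if (any(!is.na(bg) & (bg < SENSOR_RANGE[1] | bg > SENSOR_RANGE[2]))) {
    stop("glucose outside sensor range [40, 500] mg/dL")
  }
  f <- risk_f(bg)
  r <- 10 * f^2
  list(rl = ifelse(f < 0, r, 0), rh = ifelse(f > 0, r, 0))
}

# transform constants (mg/dL parameterization), kept in one place
RISK_A <- 1.509
RISK_B <- 1.084
RISK_C <- 5.381

risk_f <- function(bg) RISK_A * (log(bg)^RISK_B - RISK_C)

#' Time-in-range fractions for one day
#'
#' Percentages of non-missing readings inside the closed interval
#' \[`lo`, `hi`\], strictly above `hi`, and strictly below `lo`. The three
#' percentages partition 100 exactly.
#'
#' @param day numeric glucose readings (mg/dL), NA allowed.
#' @param lo,hi range bounds in mg/dL (defaults 70 and 180, the consensus
#'   target range).
#' @return Named numeric vector `c(in_range, above, below)` in percent, or
#'   all-`NA` if the day has no readings.
#' @export
range_fractions <- function(day, lo = 70, hi = 180) {
  x <- day[!is.na(day)]
  if (length(x) == 0) return(c(in_range = NA_real_, above = NA_real_, below = NA_real_))
  n <- length(x)
  c(in_range = 100 * sum(x >= lo & x <= hi) / n,
    above = 100 * sum(x > hi) / n,
    below = 100 * sum(x < lo) / n)
}

#' Within-day glycemic variability by SD and CV
#'
#' Sample standard deviation (n-1 denominator) of the day's readings and the
#' coefficient of variation `100 * sd / mean`.
#'
#' @param day numeric glucose readings (mg/dL), NA allowed.
#' @return Named numeric vector `c(sd, cv)`, `NA` if fewer than 2 readings.
#' @export
gv_sd_cv <- function(day) {
  x <- day[!is.na(day)]
  if (length(x) < 2) return(c(sd = NA_real_, cv = NA_real_))
  s <- sd(x)
  c(sd = s, cv = 100 * s / mean(x))
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Classic turning-point formulation: local extrema of the (unsmoothed)
#' series are found by scanning sign changes of the first difference with
#' plateaus and same-direction segments merged; consecutive extrema
#' (including the day's first and last readings as boundary extrema) define
#' excursions, and MAGE is the arithmetic mean of the excursion amplitudes
#' strictly greater than the day's standard deviation, counting both rising
#' and falling excursions. A monotone or constant day, or a day with no
#' qualifying excursion, yields 0.
#'
#' @param day numeric glucose readings (mg/dL), NA allowed (missing points
#'   are skipped, the remaining readings are treated as consecutive).
#' @param threshold_sd excursion qualification threshold; default the day's
#'   own sample SD.
#' @return MAGE in mg/dL, `NA` if fewer than 3 readings.
#' @export
mage <- function(day, threshold_sd = NULL) {
  x <- day[!is.na(day)]
  if (length(x) < 3) return(NA_real_)
  thr <- if (is.null(threshold_sd)) sd(x) else threshold_sd
  ext <- turning_points(x)
  if (length(ext) < 3) return(0) # no interior turning point: monotone/constant
  amp <- abs(diff(x[ext]))
  amp <- amp[amp > thr]
  if (length(amp) == 0) return(0)
  mean(amp)
}

# indices of alternating extrema: first point, interior turning points
# (sign changes of the run-length-merged first difference), last point
turning_points <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) == 0) return(integer(0))
  s <- sign(d[nz])
  chg <- which(diff(s) != 0)
  interior <- nz[chg] + 1L
  c(1L, interior, length(x))
}

#' J-index
#'
#' Composite of glucose level and spread: `0.001 * (mean + sd)^2` in the
#' mg/dL formulation.
#'
#' @param mean mean glucose in mg/dL (> 0).
#' @param sd glucose SD in mg/dL (>= 0).
#' @return Dimensionless J-index.
#' @export
j_index <- function(mean, sd) {
  stopifnot(all(is.na(mean) | mean > 0), all(is.na(sd) | sd >= 0))
  0.001 * (mean + sd)^2
}

#' Low and high blood-glucose indices for one day
#'
#' LBGI is the mean of the low-risk component `rl` over the day's readings;
#' HBGI the mean of the high-risk component `rh` (see [bg_risk]).
#'
#' @param day numeric glucose readings (mg/dL), NA allowed.
#' @return Named numeric vector `c(lbgi, hbgi)`, `NA` if no readings.
#' @export
lbgi_hbgi <- function(day) {
  x <- day[!is.na(day)]
  if (length(x) == 0) return(c(lbgi = NA_real_, hbgi = NA_real_))
  r <- bg_risk(x)
  c(lbgi = mean(r$rl), hbgi = mean(r$rh))
}

#' Average daily risk range (ADRR)
#'
#' For each day the daily risk range is the day's maximum low-glucose risk
#' plus its maximum high-glucose risk; ADRR is the mean of the daily risk
#' ranges across valid days.
#'
#' @param days list of numeric reading vectors, one per day (NA allowed).
#' @return ADRR (dimensionless), `NA` if no day has readings.
#' @export
adrr <- function(days) {
  drr <- vapply(days, function(day) {
    x <- day[!is.na(day)]
    if (length(x) == 0) return(NA_real_)
    r <- bg_risk(x)
    max(r$rl) + max(r$rh)
  }, numeric(1))
  drr <- drr[!is.na(drr)]
  if (length(drr) == 0) return(NA_real_)
  mean(drr)
}

#' Mean of daily differences (MODD)
#'
#' Mean absolute difference between glucose values at matched clock times on
#' consecutive days, over all grid slots and consecutive day pairs where both
#' values are present.
#'
#' @param day_matrix numeric matrix, one row per day, one column per grid
#'   slot (matched clock times); NA marks missing points.
#' @return MODD in mg/dL, `NA` if no aligned consecutive-day pair exists.
#' @export
modd <- function(day_matrix) {
  if (is.null(dim(day_matrix)) || nrow(day_matrix) < 2) return(NA_real_)
  d <- abs(day_matrix[-1, , drop = FALSE] - day_matrix[-nrow(day_matrix), , drop = FALSE])
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

#' Continuous overall net glycemic action (CONGA)
#'
#' Sample standard deviation of the differences between each reading and the
#' reading `lag_hours` earlier on the same grid, over all times where both
#' values are present.
#'
#' @param day numeric gridded readings for one day (NA allowed).
#' @param lag_hours lag in hours (default 1).
#' @param interval_min grid interval in minutes (default 15).
#' @return CONGA in mg/dL, `NA` if fewer than 2 lagged pairs exist.
#' @export
conga <- function(day, lag_hours = 1, interval_min = 15) {
  k <- as.integer(round(lag_hours * 60 / interval_min))
  if (k < 1 || length(day) <= k) return(NA_real_)
  d <- day[(k + 1):length(day)] - day[1:(length(day) - k)]
  d <- d[!is.na(d)]
  if (length(d) < 2) return(NA_real_)
  sd(d)
}

#' Per-day glycemic index table
#'
#' Computes every daily index for each subject-day of a gridded trace
#' collection: mean glucose, SD, CV, TIR \[70,180\], rTIR \[70,110\], TAR,
#' TBR, MAGE, J-index, LBGI, HBGI, CONGA and the fraction of grid points
#' present. Days with `valid_fraction` below `min_valid` keep their row but
#' carry NA indices, so they are excluded from all aggregates.
#'
#' @param traces a gridded [cgm_traces] data frame (see [resample_to_grid]);
#'   typically already restricted with [analysis_window].
#' @param conga_lag CONGA lag in hours (default 1).
#' @param min_valid minimum fraction of grid points that must be present for
#'   a day to be scored (default 0.7).
#' @return Data frame, one row per subject-day.
#' @export
daily_indices <- function(traces, conga_lag = 1, min_valid = 0.7) {
  interval <- attr(traces, "interval_min")
  if (is.null(interval)) interval <- 15
  slots_per_day <- as.integer(24 * 60 / interval)
  di <- day_index(traces)
  key <- interaction(traces$subject_id, di, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(traces)), key), function(idx) {
    day <- traces$glucose_mgdl[idx]
    vf <- sum(!is.na(day)) / slots_per_day
    rec <- data.frame(
      subject_id = traces$subject_id[idx[1]],
      cohort = traces$cohort[idx[1]],
      day_index = di[idx[1]],
      mean_glucose = NA_real_, sd = NA_real_, cv = NA_real_,
      tir = NA_real_, rtir = NA_real_, tar = NA_real_, tbr = NA_real_,
      mage = NA_real_, j_index = NA_real_, lbgi = NA_real_, hbgi = NA_real_,
      conga_n = NA_real_, valid_fraction = vf,
      stringsAsFactors = FALSE
    )
    if (vf < min_valid || sum(!is.na(day)) < 2) return(rec)
    rf <- range_fractions(day, 70, 180)
    rrf <- range_fractions(day, 70, 110)
    sc <- gv_sd_cv(day)
    lh <- lbgi_hbgi(day)
    rec$mean_glucose <- mean(day, na.rm = TRUE)
    rec$sd <- sc[["sd"]]; rec$cv <- sc[["cv"]]
    rec$tir <- rf[["in_range"]]; rec$tar <- rf[["above"]]; rec$tbr <- rf[["below"]]
    rec$rtir <- rrf[["in_range"]]
    rec$mage <- mage(day)
    rec$j_index <- j_index(rec$mean_glucose, rec$sd)
    rec$lbgi <- lh[["lbgi"]]; rec$hbgi <- lh[["hbgi"]]
    rec$conga_n <- conga(day, lag_hours = conga_lag, interval_min = interval)
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$day_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subject cross-day aggregates
#'
#' Cross-day indices per subject: ADRR and MODD computed from the gridded
#' trace over valid days, plus the mean of each daily index across valid
#' days of the analysis window.
#'
#' @param traces a gridded [cgm_traces] data frame (analysis window applied).
#' @param daily optional precomputed [daily_indices] table for `traces`.
#' @param conga_lag,min_valid passed to [daily_indices] when `daily` is NULL.
#' @return Data frame, one row per subject, with `adrr`, `modd` and
#'   `mean_<index>` columns.
#' @export
subject_summaries <- function(traces, daily = NULL, conga_lag = 1, min_valid = 0.7) {
  interval <- attr(traces, "interval_min")
  if (is.null(interval)) interval <- 15
  slots_per_day <- as.integer(24 * 60 / interval)
  if (is.null(daily)) daily <- daily_indices(traces, conga_lag, min_valid)
  di <- day_index(traces)
  slot <- slot_of_day(traces$timestamp, interval)
  rows <- lapply(split(seq_len(nrow(traces)), traces$subject_id), function(idx) {
    sid <- traces$subject_id[idx[1]]
    drec <- daily[daily$subject_id == sid, , drop = FALSE]
    valid_days <- drec$day_index[!is.na(drec$mean_glucose)]
    keep <- idx[di[idx] %in% valid_days]
    day_list <- split(traces$glucose_mgdl[keep], di[keep])
    # day x slot matrix on matched clock times for MODD
    mat <- matrix(NA_real_, nrow = length(day_list), ncol = slots_per_day)
    for (i in seq_along(day_list)) {
      ix <- keep[di[keep] == as.integer(names(day_list)[i])]
      mat[i, slot[ix]] <- traces$glucose_mgdl[ix]
    }
    # MODD pairs must be consecutive calendar days
    dd <- as.integer(names(day_list))
    mats <- if (length(dd) >= 2) {
      consec <- which(diff(dd) == 1)
      if (length(consec) == 0) mat[0, , drop = FALSE] else mat
    } else mat
    if (length(dd) >= 2 && any(diff(dd) > 1)) {
      # split into consecutive runs and compute MODD over within-run pairs
      runs <- split(seq_along(dd), cumsum(c(1, diff(dd) != 1)))
      diffs <- unlist(lapply(runs, function(r) {
        if (length(r) < 2) return(numeric(0))
        m <- mat[r, , drop = FALSE]
        d <- abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
        d[!is.na(d)]
      }))
      modd_val <- if (length(diffs)) mean(diffs) else NA_real_
    } else {
      modd_val <- modd(mats)
    }
    agg <- colMeans(drec[, c("mean_glucose", "sd", "cv", "tir", "rtir", "tar",
                             "tbr", "mage", "j_index", "lbgi", "hbgi", "conga_n")],
                    na.rm = TRUE)
    agg[is.nan(agg)] <- NA_real_
    out <- data.frame(subject_id = sid, cohort = drec$cohort[1],
                      n_valid_days = length(valid_days),
                      adrr = adrr(day_list), modd = modd_val,
                      stringsAsFactors = FALSE)
    for (nm in names(agg)) out[[paste0("mean_", nm)]] <- agg[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

slot_of_day <- function(timestamp, interval_min) {
  mins <- as.numeric(timestamp - trunc(timestamp, units = "days"), units = "mins")
  as.integer(round(mins / interval_min)) %% as.integer(24 * 60 / interval_min) + 1L
}
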