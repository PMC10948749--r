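# Synthetic two-cohort CGM study generator.
#
# Each subject carries a single latent dysglycemia factor z ~ N(0,1) drawn
# once; z raises the glucose baseline and meal-excursion amplitude and loads
# on the biomarker panel, which is what induces the positive GV-biomarker
# correlations seen in pre-diabetic cohorts.

#' Simulation configuration
#'
#' Builds the configuration object for [simulate_cohorts]. Cohort archetype
#' parameters (baseline glucose, circadian shape, meal model, AR(1) noise,
#' across-day drift, biomarker and activity distributions) live in a preset
#' file; the packaged default presets are calibrated so that the full
#' pipeline reproduces the cohort-level summary statistics of a 14-day
#' healthy / pre-diabetic CGM study (53 + 52 subjects, 15-minute sampling).
#'
#' @param n_healthy,n_prediabetic cohort sizes (defaults 53 and 52).
#' @param days days of wear per subject (default 14).
#' @param interval_min sampling interval in minutes (default 15).
#' @param seed base RNG seed.
#' @param target_r nominal latent-factor correlation between realized GV and
#'   the loaded biomarkers in the pre-diabetic cohort (default 0.4);
#'   informational unless inconsistent with `latent_loading`.
#' @param latent_loading global multiplier on all biomarker latent loadings
#'   (default 1; 0 decouples biomarkers from glucose dynamics).
#' @param presets path to a YAML preset file or a preset list; default the
#'   packaged `cohort_presets.yaml`.
#' @param preset_overrides nested list of per-cohort parameter overrides,
#'   e.g. `list(healthy = list(noise_sd = 0))`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_healthy = 53, n_prediabetic = 52, days = 14,
                       interval_min = 15, seed = 1, target_r = 0.4,
                       latent_loading = 1, presets = NULL,
                       preset_overrides = NULL) {
  if (is.null(presets)) {
    presets <- system.file("extdata", "cohort_presets.yaml", package = "cgmetrics")
  }
  pre <- if (is.character(presets)) yaml::read_yaml(presets) else presets
  if (!all(c("healthy", "prediabetic") %in% names(pre))) {
    stop("presets must define 'healthy' and 'prediabetic' archetypes")
  }
  if (!is.null(preset_overrides)) {
    for (co in names(preset_overrides)) {
      pre[[co]] <- modifyList(pre[[co]], preset_overrides[[co]])
    }
  }
  if (target_r != 0 && latent_loading == 0) {
    stop("inconsistent config: target_r != 0 requires a nonzero latent_loading")
  }
  stopifnot(days >= 1, interval_min > 0, n_healthy >= 0, n_prediabetic >= 0)
  for (co in c("healthy", "prediabetic")) {
    p <- pre[[co]]
    if (p$noise_rho < 0 || p$noise_rho >= 1) stop("noise_rho must be in [0,1)")
    if (p$noise_sd < 0 || p$baseline_sd_between < 0 || p$baseline_sd_day < 0) {
      stop("all SDs must be >= 0")
    }
  }
  structure(list(
    n_healthy = n_healthy, n_prediabetic = n_prediabetic, days = days,
    interval_min = interval_min, seed = seed, target_r = target_r,
    latent_loading = latent_loading, presets = pre
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d healthy + %d pre-diabetic, %d days @ %d min, seed %s\n",
              x$n_healthy, x$n_prediabetic, x$days, x$interval_min,
              format(x$seed)))
  invisible(x)
}

#' Simulate one subject's CGM trace
#'
#' Glucose is the clipped sum of a subject baseline (latent factor, random
#' intercept, per-day jitter and linear across-day drift), a cosine circadian
#' rhythm with an extra nocturnal dip, three daily meal pulses with
#' lognormal amplitudes and gamma-like rise/decay, and stationary AR(1)
#' sensor noise. Deterministic given `(config, cohort, seed)`.
#'
#' @param config a [sim_config].
#' @param cohort `"healthy"` or `"prediabetic"`.
#' @param seed integer seed for this subject.
#' @param subject_id identifier for the returned trace.
#' @param start first day's date (trace starts at its local midnight).
#' @return A [cgm_traces] data frame with attribute `latent` (the subject's
#'   dysglycemia factor z).
#' @export
simulate_subject <- function(config, cohort = c("healthy", "prediabetic"),
                             seed = 1, subject_id = "S1",
                             start = as.Date("2022-10-01")) {
  cohort <- match.arg(cohort)
  set.seed(as.integer(seed %% .Machine$integer.max))
  z <- rnorm(1)
  tr <- sim_subject_core(config, cohort, z, subject_id, start)
  attr(tr, "latent") <- z
  tr
}

# draws from the current RNG stream; z supplied by the caller
sim_subject_core <- function(config, cohort, z, subject_id, start) {
  p <- config$presets[[cohort]]
  days <- config$days
  step <- config$interval_min
  n_day <- as.integer(24 * 60 / step)
  n <- n_day * days
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * step * 60
  hour <- (as.numeric(ts - t0, units = "hours")) %% 24
  day <- rep(seq_len(days), each = n_day)

  base_subj <- p$baseline_mean + p$baseline_latent * z +
    rnorm(1, 0, p$baseline_sd_between)
  day_jit <- rnorm(days, 0, p$baseline_sd_day)
  baseline <- base_subj + day_jit[day] + p$drift_baseline_per_day * (day - 1)

  circ <- p$circadian_amplitude * cos(2 * pi * (hour - p$circadian_peak_hour) / 24) -
    p$nocturnal_dip * exp(-((hour - p$nocturnal_dip_hour) / p$nocturnal_dip_width)^2)

  amp_scale <- pmax(1 + p$meal_amp_latent * z, 0.2)
  meals <- numeric(n)
  t_rel <- as.numeric(ts - t0, units = "mins")
  for (d in seq_len(days)) {
    drift_fac <- max(1 + p$drift_amp_per_day * (d - 1), 0.1)
    for (m in seq_along(p$meal_times)) {
      t_meal <- (d - 1) * 1440 + p$meal_times[m] * 60 +
        rnorm(1, 0, p$meal_time_jitter_sd * 60)
      amp <- if (p$meal_amp_median <= 0) 0 else
        rlnorm(1, log(p$meal_amp_median), p$meal_amp_sdlog) *
          amp_scale * drift_fac
      u <- (t_rel - t_meal) / p$meal_tau_min
      on <- u > 0 & u < 12
      meals[on] <- meals[on] + amp * u[on] * exp(1 - u[on])
    }
  }

  eps <- numeric(n)
  if (p$noise_sd > 0) {
    w <- rnorm(n)
    eps[1] <- w[1] * p$noise_sd
    rho <- p$noise_rho
    innov_sd <- p$noise_sd * sqrt(1 - rho^2)
    for (i in 2:n) eps[i] <- rho * eps[i - 1] + innov_sd * w[i]
  }

  glucose <- pmin(pmax(baseline + circ + meals + eps, SENSOR_RANGE[1]),
                  SENSOR_RANGE[2])
  tr <- cgm_traces(rep(subject_id, n), rep(cohort, n), ts, glucose)
  attr(tr, "interval_min") <- step
  tr
}

#' Simulate the full two-cohort study
#'
#' Generates CGM traces, the per-subject biomarker panel (HbA1c, 2-h OGTT,
#' HOMA-IR via simulated fasting insulin, Hs-CRP, cortisol, baseline and
#' end-of-study fasting glucose) and the daily activity table (steps, heart
#' rate, sleep). Screen-defining biomarkers are drawn inside the ADA
#' eligibility bands of each cohort (healthy: FBG 79--99 mg/dL, HbA1c
#' 4.0--5.6%, OGTT < 140; pre-diabetic: FBG 100--125, HbA1c 5.7--6.4,
#' OGTT 140--199). The shared latent factor links each subject's realized
#' glycemic variability to HbA1c, OGTT, HOMA-IR and Hs-CRP.
#'
#' @param config a [sim_config].
#' @return A `cgm_cohorts` list with elements `traces`, `panel`, `activity`,
#'   `latent` (per-subject z) and `config`.
#' @export
simulate_cohorts <- function(config) {
  plan <- data.frame(
    cohort = rep(c("healthy", "prediabetic"),
                 c(config$n_healthy, config$n_prediabetic)),
    stringsAsFactors = FALSE
  )
  if (nrow(plan) == 0) stop("both cohorts empty")
  plan$subject_id <- c(sprintf("H%03d", seq_len(config$n_healthy)),
                       sprintf("P%03d", seq_len(config$n_prediabetic)))

  traces <- vector("list", nrow(plan))
  panel <- vector("list", nrow(plan))
  activity <- vector("list", nrow(plan))
  latent <- numeric(nrow(plan))
  base_seed <- as.integer(config$seed %% 1000003L)
  for (i in seq_len(nrow(plan))) {
    co <- plan$cohort[i]
    sid <- plan$subject_id[i]
    set.seed((base_seed * 1009L + i * 7919L) %% .Machine$integer.max)
    z <- rnorm(1)
    latent[i] <- z
    tr <- sim_subject_core(config, co, z, sid, as.Date("2022-10-01"))
    traces[[i]] <- tr
    p <- config$presets[[co]]
    panel[[i]] <- sim_panel_row(p, sid, co, z, config$latent_loading)
    activity[[i]] <- sim_activity_rows(p, sid, z, config$latent_loading,
                                       config$days, as.Date("2022-10-01"))
  }
  traces <- do.call(rbind, lapply(traces, as.data.frame))
  class(traces) <- c("cgm_traces", "data.frame")
  attr(traces, "interval_min") <- config$interval_min
  attr(traces, "origin") <- trace_origin(traces)
  out <- list(traces = traces, panel = do.call(rbind, panel),
              activity = do.call(rbind, activity),
              latent = setNames(latent, plan$subject_id), config = config)
  class(out) <- "cgm_cohorts"
  out
}

#' @export
print.cgm_cohorts <- function(x, ...) {
  tab <- table(x$panel$cohort)
  cat(sprintf("<cgm_cohorts> %s subjects (%s), %d CGM readings\n",
              nrow(x$panel), paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$traces)))
  invisible(x)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(1, plo, phi), mean, sd)
}

sim_panel_row <- function(p, sid, cohort, z, loading) {
  b <- p$biomarkers
  ld <- function(nm) loading * b[[nm]]$loading
  hba1c <- rtruncnorm1(b$hba1c$mean + ld("hba1c") * z, b$hba1c$sd,
                       b$hba1c$lo, b$hba1c$hi)
  ogtt <- rtruncnorm1(b$ogtt_2h$mean + ld("ogtt_2h") * z, b$ogtt_2h$sd,
                      b$ogtt_2h$lo, b$ogtt_2h$hi)
  fbg0 <- rtruncnorm1(b$fbg$mean + ld("fbg") * z, b$fbg$sd, b$fbg$lo, b$fbg$hi)
  insulin <- rlnorm(1, b$insulin$meanlog + ld("insulin") * z, b$insulin$sdlog)
  hscrp <- rlnorm(1, b$hscrp$meanlog + ld("hscrp") * z, b$hscrp$sdlog)
  cortisol <- rtruncnorm1(b$cortisol$mean + ld("cortisol") * z, b$cortisol$sd,
                          b$cortisol$lo, b$cortisol$hi)
  fbg_end <- max(fbg0 + rnorm(1, b$fbg_end_delta$mean, b$fbg_end_delta$sd), 50)
  data.frame(subject_id = sid, cohort = cohort, hba1c = hba1c, ogtt_2h = ogtt,
             homa_ir = homa_ir(fbg0, insulin), hscrp = hscrp,
             cortisol = cortisol, fbg_baseline = fbg0, fbg_end = fbg_end,
             stringsAsFactors = FALSE)
}

sim_activity_rows <- function(p, sid, z, loading, days, start) {
  a <- p$activity
  steps <- pmax(round(rnorm(days, a$steps$mean + loading * a$steps$loading * z,
                            a$steps$sd)), 0)
  hr <- pmax(rnorm(days, a$hr$mean + loading * a$hr$loading * z, a$hr$sd), 40)
  sleep <- pmin(pmax(rnorm(days, a$sleep$mean + loading * a$sleep$loading * z,
                           a$sleep$sd), 120), 720)
  data.frame(subject_id = sid, date = as.character(start + seq_len(days) - 1),
             steps = steps, hr_bpm = round(hr, 1), sleep_min = round(sleep),
             stringsAsFactors = FALSE)
}

#' Homeostasis-model insulin-resistance index (HOMA-IR)
#'
#' `HOMA-IR = fasting glucose (mg/dL) * fasting insulin (uU/mL) / 405`.
#'
#' @param fasting_glucose fasting plasma glucose in mg/dL (> 0).
#' @param fasting_insulin fasting insulin in uU/mL (> 0).
#' @return Dimensionless HOMA-IR.
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0)) {
    stop("fasting glucose and insulin must be strictly positive")
  }
  fasting_glucose * fasting_insulin / 405
}
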