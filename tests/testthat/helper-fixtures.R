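# Fixture builders and independent brute-force oracles for the index engine.
# Oracles are written as naive loops, deliberately unlike the package code.

make_trace <- function(glucose, start = "2022-10-01 00:00:00",
                       interval_min = 15, subject_id = "S1",
                       cohort = "healthy") {
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- t0 + (seq_along(glucose) - 1) * interval_min * 60
  tr <- cgm_traces(rep(subject_id, length(glucose)), rep(cohort, length(glucose)),
                   ts, glucose)
  attr(tr, "interval_min") <- interval_min
  tr
}

# random gridded day(s): baseline + a few bumps + noise, with optional gaps
random_day <- function(n = 96, miss_frac = 0, rng = NULL) {
  x <- 100 + cumsum(rnorm(n, 0, 6))
  x <- pmin(pmax(x, 40), 500)
  if (miss_frac > 0) x[sample(n, floor(miss_frac * n))] <- NA
  x
}

oracle_risk <- function(bg) {
  f <- 1.509 * (log(bg)^1.084 - 5.381)
  r <- 10 * f * f
  if (f < 0) c(rl = r, rh = 0) else if (f > 0) c(rl = 0, rh = r) else c(rl = 0, rh = 0)
}

oracle_mage <- function(x, thr = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  if (is.null(thr)) thr <- sd(x)
  # collapse exact repeats, then find interior extrema by neighbour comparison
  y <- x[c(TRUE, diff(x) != 0)]
  if (length(y) < 3) return(0)
  ext <- y[1]
  for (i in 2:(length(y) - 1)) {
    if ((y[i] > y[i - 1] && y[i] > y[i + 1]) ||
        (y[i] < y[i - 1] && y[i] < y[i + 1])) ext <- c(ext, y[i])
  }
  ext <- c(ext, y[length(y)])
  if (length(ext) < 3) return(0)
  amps <- numeric(0)
  for (i in 2:length(ext)) amps <- c(amps, abs(ext[i] - ext[i - 1]))
  amps <- amps[amps > thr]
  if (length(amps) == 0) 0 else mean(amps)
}

oracle_conga <- function(x, lag_hours = 1, interval_min = 15) {
  k <- round(lag_hours * 60 / interval_min)
  diffs <- numeric(0)
  for (t in seq_along(x)) {
    if (t - k >= 1 && !is.na(x[t]) && !is.na(x[t - k])) {
      diffs <- c(diffs, x[t] - x[t - k])
    }
  }
  if (length(diffs) < 2) NA_real_ else sd(diffs)
}

oracle_modd <- function(mat) {
  diffs <- numeric(0)
  if (nrow(mat) < 2) return(NA_real_)
  for (d in 1:(nrow(mat) - 1)) {
    for (s in seq_len(ncol(mat))) {
      a <- mat[d, s]; b <- mat[d + 1, s]
      if (!is.na(a) && !is.na(b)) diffs <- c(diffs, abs(b - a))
    }
  }
  if (length(diffs) == 0) NA_real_ else mean(diffs)
}

oracle_adrr <- function(days) {
  drr <- numeric(0)
  for (day in days) {
    day <- day[!is.na(day)]
    if (length(day) == 0) next
    rls <- numeric(0); rhs <- numeric(0)
    for (g in day) {
      r <- oracle_risk(g)
      rls <- c(rls, r["rl"]); rhs <- c(rhs, r["rh"])
    }
    drr <- c(drr, max(rls) + max(rhs))
  }
  if (length(drr) == 0) NA_real_ else mean(drr)
}

# tiny deterministic simulation config for fast pipeline tests
small_config <- function(seed = 1, n_healthy = 6, n_prediabetic = 6, days = 4) {
  sim_config(n_healthy = n_healthy, n_prediabetic = n_prediabetic,
             days = days, seed = seed)
}
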