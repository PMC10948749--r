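test_that("range fractions partition readings with closed in-range bounds", {
  expect_equal(range_fractions(rep(100, 10)), c(in_range = 100, above = 0, below = 0))
  expect_equal(range_fractions(c(rep(60, 5), rep(100, 5))),
               c(in_range = 50, above = 0, below = 50))
  # exhaustive count: only 90 lies in [70,110]; 120 and 190 are above, 65 below
  expect_equal(range_fractions(c(65, 90, 120, 190), 70, 110),
               c(in_range = 25, above = 50, below = 25))
  # boundary values count as in range
  expect_equal(range_fractions(c(70, 180))[["in_range"]], 100)
  expect_true(all(is.na(range_fractions(c(NA_real_, NA_real_)))))
})

test_that("sd/cv use the sample SD and behave under scaling", {
  expect_equal(gv_sd_cv(rep(100, 5)), c(sd = 0, cv = 0))
  r <- gv_sd_cv(c(90, 110))
  expect_equal(r[["sd"]], sqrt(200), tolerance = 1e-12)
  expect_equal(r[["cv"]], 100 * sqrt(200) / 100, tolerance = 1e-12)
  set.seed(7)
  x <- runif(30, 80, 160)
  expect_equal(gv_sd_cv(2 * x)[["sd"]], 2 * gv_sd_cv(x)[["sd"]])
  expect_equal(gv_sd_cv(2 * x)[["cv"]], gv_sd_cv(x)[["cv"]])
  expect_true(all(is.na(gv_sd_cv(100))))
})

test_that("MAGE averages qualifying turning-point amplitudes", {
  expect_equal(mage(rep(100, 10)), 0)
  expect_equal(mage(seq(80, 160, by = 10)), 0) # monotone: no turning point
  expect_equal(mage(c(100, 125, 150, 125, 100)), 50) # single excursion, SD ~20
  # two-excursion profile against hand-computed amplitudes
  x <- c(100, 150, 100, 140, 100)
  expect_equal(mage(x), mean(c(50, 50, 40, 40))) # all exceed SD 24.5
  # plateau at the peak is merged, not double-counted
  expect_equal(mage(c(100, 150, 150, 100)), 50)
  # explicit threshold overrides the day's SD
  expect_equal(mage(c(100, 150, 100, 110, 100), threshold_sd = 45), 50)
})

test_that("J-index matches its closed form and is monotone", {
  expect_equal(j_index(100, 0), 10)
  expect_equal(j_index(100, 20), 14.4)
  expect_true(j_index(120, 20) > j_index(100, 20))
  expect_true(j_index(100, 30) > j_index(100, 20))
  expect_error(j_index(-5, 0))
})

test_that("risk transform splits low and high risk around its root", {
  r <- bg_risk(112.5)
  expect_lt(r$rl + r$rh, 1e-3)
  expect_true(bg_risk(40)$rl > 0 && bg_risk(40)$rh == 0)
  expect_true(bg_risk(400)$rh > 0 && bg_risk(400)$rl == 0)
  expect_error(bg_risk(30), "sensor range")
  # pointwise rl * rh = 0 and f monotone over the sensor range
  bg <- seq(40, 500, by = 1)
  rr <- bg_risk(bg)
  expect_true(all(rr$rl * rr$rh == 0))
  f <- sqrt(rr$rh / 10) - sqrt(rr$rl / 10)
  expect_true(all(diff(f) > 0))
})

test_that("LBGI/HBGI are the mean per-reading risks", {
  lh <- lbgi_hbgi(rep(112.5, 10))
  expect_true(all(lh < 1e-3))
  expect_equal(lbgi_hbgi(c(80, 95, 110))[["hbgi"]], 0)
  set.seed(11)
  day <- runif(50, 45, 350)
  ora <- rowMeans(sapply(day, oracle_risk))
  lh2 <- lbgi_hbgi(day)
  expect_equal(lh2[["lbgi"]], ora[["rl"]], tolerance = 1e-12)
  expect_equal(lh2[["hbgi"]], ora[["rh"]], tolerance = 1e-12)
})

test_that("ADRR equals the mean of daily risk ranges", {
  expect_lt(adrr(list(rep(112.5, 4))), 1e-3)
  one_day <- c(70, 100, 150)
  r <- bg_risk(one_day)
  expect_equal(adrr(list(one_day)), max(r$rl) + max(r$rh))
  set.seed(13)
  days <- replicate(3, runif(24, 50, 300), simplify = FALSE)
  days[[2]][5:10] <- NA
  expect_equal(adrr(days), oracle_adrr(days), tolerance = 1e-12)
  expect_true(is.na(adrr(list(c(NA_real_, NA_real_)))))
})

test_that("MODD measures matched-time day-to-day differences", {
  mat <- rbind(rep(100, 8), rep(100, 8))
  expect_equal(modd(mat), 0)
  expect_equal(modd(rbind(seq(90, 160, by = 10), seq(90, 160, by = 10) + 10)), 10)
  set.seed(17)
  m <- matrix(runif(3 * 12, 60, 250), nrow = 3)
  m[sample(length(m), 6)] <- NA
  expect_equal(modd(m), oracle_modd(m), tolerance = 1e-12)
  expect_true(is.na(modd(matrix(100, 1, 4))))
})

test_that("CONGA is the SD of lagged within-day differences", {
  expect_equal(conga(rep(100, 96)), 0)
  # 24-h periodic signal, lag = one period: differences vanish
  x <- 120 + 30 * sin(2 * pi * (0:191) / 96)
  expect_equal(conga(x, lag_hours = 24), 0)
  set.seed(19)
  day <- runif(12, 70, 200)
  expect_equal(conga(day, lag_hours = 1, interval_min = 15),
               oracle_conga(day, 1, 15), tolerance = 1e-12)
  expect_true(is.na(conga(runif(4, 80, 120), lag_hours = 4, interval_min = 60)))
})

test_that("translation invariance: level shifts move only the mean", {
  set.seed(23)
  for (i in 1:25) {
    x <- random_day(48, miss_frac = 0.1)
    shift <- runif(1, -15, 15)
    y <- x + shift
    y <- pmin(pmax(y, 40), 500)
    if (!identical(y, x + shift)) next # skip cases hitting the clip bounds
    expect_equal(gv_sd_cv(y)[["sd"]], gv_sd_cv(x)[["sd"]], tolerance = 1e-9)
    expect_equal(mage(y, threshold_sd = 10), mage(x, threshold_sd = 10),
                 tolerance = 1e-9)
    expect_equal(conga(y), conga(x), tolerance = 1e-9)
    expect_equal(mean(y, na.rm = TRUE) - mean(x, na.rm = TRUE), shift,
                 tolerance = 1e-9)
  }
})

test_that("daily index table gates on coverage and satisfies its invariants", {
  set.seed(29)
  glu <- 100 + 20 * sin(2 * pi * (0:(96 * 3 - 1)) / 96) + rnorm(96 * 3, 0, 5)
  tr <- make_trace(pmin(pmax(glu, 40), 500))
  g <- resample_to_grid(tr)
  d <- daily_indices(g, min_valid = 0.7)
  ok <- !is.na(d$mean_glucose)
  expect_true(any(ok))
  expect_equal(d$tir[ok] + d$tar[ok] + d$tbr[ok], rep(100, sum(ok)),
               tolerance = 1e-9)
  expect_true(all(d$rtir[ok] <= d$tir[ok] + 1e-12))
  expect_equal(d$cv[ok], 100 * d$sd[ok] / d$mean_glucose[ok], tolerance = 1e-12)
  expect_true(all(d$mage[ok] >= 0 & d$lbgi[ok] >= 0 & d$hbgi[ok] >= 0))

  # knock out half of day 2: that day must be excluded, not guessed at
  glu2 <- glu
  glu2[97:168] <- NA
  tr2 <- make_trace(glu2)
  tr2 <- tr2[!is.na(tr2$glucose_mgdl), ]
  class(tr2) <- c("cgm_traces", "data.frame")
  d2 <- daily_indices(resample_to_grid(tr2), min_valid = 0.7)
  expect_true(is.na(d2$mean_glucose[d2$day_index == 2]))
  expect_lt(d2$valid_fraction[d2$day_index == 2], 0.7)
})

test_that("subject summaries aggregate over valid days only", {
  set.seed(31)
  glu <- 110 + rnorm(96 * 4, 0, 12)
  tr <- make_trace(pmin(pmax(glu, 40), 500))
  g <- resample_to_grid(tr)
  w <- analysis_window(g)
  d <- daily_indices(w)
  s <- subject_summaries(w, daily = d)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_valid_days, sum(!is.na(d$mean_glucose)))
  expect_equal(s$mean_mean_glucose, mean(d$mean_glucose, na.rm = TRUE))
  expect_true(s$adrr >= 0 && s$modd >= 0)
  # MODD against the oracle on the day x slot matrix
  di <- day_index(w)
  mat <- do.call(rbind, split(w$glucose_mgdl, di))
  expect_equal(s$modd, oracle_modd(mat), tolerance = 1e-9)
})
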