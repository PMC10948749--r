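test_that("outlier rules follow the +/-3SD and 3xIQR fences, one pass", {
  # type-7 quartiles of {1,2,3,100}: Q1=1.75, Q3=27.25, fences far out
  r <- remove_outliers(c(1, 2, 3, 100), "nonparametric")
  expect_equal(r$n_removed, 0L)
  expect_equal(r$values, c(1, 2, 3, 100))

  set.seed(8)
  x <- c(rnorm(50), 10)
  rn <- remove_outliers(x, "normal")
  expect_true(10 %in% rn$removed)
  expect_equal(rn$n_removed, 1L)
  # a second pass in the same mode removes nothing more on this fixture
  rn2 <- remove_outliers(rn$values, "normal")
  expect_equal(rn2$n_removed, 0L)

  same <- remove_outliers(rep(5, 10), "normal")
  expect_equal(same$values, rep(5, 10))
  expect_warning(remove_outliers(c(1, 2, 3), "normal"), "fewer than 4")
})

test_that("correlation method is gated on normality of both variables", {
  set.seed(12)
  x <- rnorm(40)
  lin <- correlate(x, 2 * x + 1)
  expect_equal(lin$method, "pearson")
  expect_equal(lin$r, 1)

  mono <- correlate(x, exp(4 * x))
  expect_equal(mono$method, "spearman")
  expect_equal(mono$r, 1)

  expect_true(is.na(correlate(x, rep(1, 40))$r))
  expect_error(correlate(1:4, 1:4), "at least 5")

  # affine invariance of Pearson, monotone invariance of Spearman
  y <- x + rnorm(40, 0, 0.5)
  expect_equal(correlate(3 * x - 2, y)$r, correlate(x, y)$r, tolerance = 1e-12)
  u <- rexp(40); v <- u + rexp(40, 5) # skewed: both gate to Spearman
  expect_equal(correlate(u^3, v)$r, correlate(u, v)$r, tolerance = 1e-12)
})

test_that("independent draws rarely show spurious correlation", {
  set.seed(14)
  rs <- replicate(100, cor(rnorm(50), rnorm(50)))
  expect_gte(mean(abs(rs) < 0.3), 0.95)
})

test_that("group x day comparison detects shifts and is label-symmetric", {
  set.seed(16)
  df <- data.frame(
    cohort = rep(c("healthy", "prediabetic"), each = 40 * 4),
    day_index = rep(rep(2:5, each = 40), 2),
    subject = seq_len(320)
  )
  df$value <- rnorm(320, 100, 5) + ifelse(df$cohort == "prediabetic", 10, 0)
  cmp <- compare_groups_over_days(df, "value")
  expect_lt(cmp$p_cohort, 0.001)
  expect_equal(nrow(cmp$lsm), 8)
  expect_true(all(cmp$lsm$lower <= cmp$lsm$lsmean & cmp$lsm$lsmean <= cmp$lsm$upper))
  # per-day LSM difference close to the injected 10 mg/dL shift
  w <- reshape(cmp$lsm[, c("cohort", "day_index", "lsmean")],
               idvar = "day_index", timevar = "cohort", direction = "wide")
  expect_equal(mean(w$lsmean.prediabetic - w$lsmean.healthy), 10, tolerance = 1.5)

  # relabeling swaps LSMs and keeps the p-values
  df2 <- df
  df2$cohort <- ifelse(df$cohort == "healthy", "prediabetic", "healthy")
  cmp2 <- compare_groups_over_days(df2, "value")
  expect_equal(cmp2$p_cohort, cmp$p_cohort, tolerance = 1e-9)
  expect_equal(sort(cmp2$lsm$lsmean), sort(cmp$lsm$lsmean), tolerance = 1e-9)

  df3 <- df[df$cohort == "healthy", ]
  expect_error(compare_groups_over_days(df3, "value"), "two cohorts")
})

test_that("ANCOVA recovers an additive cohort effect and degrades gracefully", {
  set.seed(18)
  # end tracks baseline exactly up to tiny noise: adjusted effect ~ 0
  base <- rnorm(60, 100, 8)
  co <- rep(c("healthy", "prediabetic"), each = 30)
  r0 <- ancova_endpoint(base + rnorm(60, 0, 1e-6), base, co)
  expect_lt(abs(r0$effect), 0.01)
  expect_gt(r0$p_value, 0.05) # no spurious cohort effect

  # recovery of a true +5 shift: CI covers it in most replicates
  cover <- replicate(25, {
    b <- rnorm(60, 100, 8)
    e <- b + 5 * (co == "prediabetic") + rnorm(60, 0, 3)
    ci <- ancova_endpoint(e, b, co)$ci
    ci[1] <= 5 && 5 <= ci[2]
  })
  expect_gte(mean(cover), 0.84)

  expect_warning(rc <- ancova_endpoint(rnorm(20), rep(1, 20),
                                       rep(c("a", "b"), each = 10)),
                 "constant baseline")
  expect_false(rc$adjusted)
})

test_that("ROC separation is oriented and behaves at the extremes", {
  co <- rep(c("healthy", "prediabetic"), each = 20)
  perfect <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  expect_equal(roc_separation(perfect, co)$auc, 1)

  set.seed(22)
  null_vals <- rnorm(40)
  auc0 <- roc_separation(null_vals, co)$auc
  se <- sqrt((20 + 20 + 1) / (12 * 20 * 20))
  expect_lt(abs(auc0 - 0.5), 3 * se)

  # an index that is *lower* in pre-diabetics is re-oriented
  rev_vals <- c(rnorm(20, 10, 1), rnorm(20, 0, 1))
  expect_gt(roc_separation(rev_vals, co)$auc, 0.9)
  expect_error(roc_separation(rnorm(5), rep("healthy", 5)), "both cohorts")
})

test_that("correlation grid covers every index x marker x cohort cell", {
  sim <- simulate_cohorts(small_config(seed = 6, n_healthy = 12,
                                       n_prediabetic = 12, days = 4))
  su <- subject_summaries(analysis_window(resample_to_grid(sim$traces),
                                          last_day = 4))
  grid <- correlation_grid(su, sim$panel)
  expect_equal(nrow(grid), 7 * 3 * 2)
  expect_true(all(abs(grid$r) <= 1, na.rm = TRUE))
  expect_true(all(grid$method %in% c("pearson", "spearman"), na.rm = TRUE))
  gridBH <- correlation_grid(su, sim$panel, adjust = "BH")
  expect_true(all(gridBH$p_adj >= gridBH$p_value - 1e-12, na.rm = TRUE))
})
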