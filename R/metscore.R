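# Transparent daily metabolic-score surrogate.
#
# A weighted composite of the three ingredient families a daily metabolic
# score is built from -- within-day glycemic variability, dwell time in the
# tight 70-110 mg/dL target band, and mean glucose -- each mapped to a 0-100
# subscore. The functional form is this package's own, explicit definition;
# it makes no claim of numerical agreement with any proprietary score.

#' Compute the daily metabolic score
#'
#' For each subject-day of a [daily_indices] table:
#' * `tir_subscore` is the restricted time in range (percent of readings in
#'   70--110 mg/dL) itself;
#' * `mean_subscore` is 100 on the 70--110 mg/dL anchor band and falls
#'   linearly to 0 at the outer anchors (`anchors$mean_lo_zero`,
#'   `anchors$mean_hi_zero`);
#' * `gv_subscore` is `100 * (1 - min(cv / cv_max, 1))` with `cv_max`
#'   defaulting to the 36% variability consensus threshold.
#'
#' The score is the weighted sum of the three subscores; default weights
#' 0.40 (GV), 0.35 (tight TIR), 0.25 (mean glucose).
#'
#' @param daily a [daily_indices] table (or any data frame with columns
#'   `mean_glucose`, `cv`, `rtir`).
#' @param weights numeric length-3 vector `c(gv, tir, mean)`, non-negative,
#'   summing to 1.
#' @param anchors list with `band` (the full-credit glucose band, default
#'   `c(70, 110)`), `mean_lo_zero` (default 40), `mean_hi_zero` (default
#'   250) and `cv_max` (default 36).
#' @return The input with columns `gv_subscore`, `tir_subscore`,
#'   `mean_subscore` and `metscore` appended; undefined days stay `NA`.
#' @export
compute_metscore <- function(daily,
                             weights = c(gv = 0.40, tir = 0.35, mean = 0.25),
                             anchors = list(band = c(70, 110),
                                            mean_lo_zero = 40,
                                            mean_hi_zero = 250,
                                            cv_max = 36)) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be 3 non-negative values summing to 1")
  }
  a <- modifyList(list(band = c(70, 110), mean_lo_zero = 40,
                       mean_hi_zero = 250, cv_max = 36), anchors)
  if (a$mean_lo_zero >= a$band[1] || a$mean_hi_zero <= a$band[2]) {
    stop("outer anchors must lie outside the full-credit band")
  }
  m <- daily$mean_glucose
  mean_sub <- ifelse(m < a$band[1],
                     100 * pmax((m - a$mean_lo_zero) / (a$band[1] - a$mean_lo_zero), 0),
                     ifelse(m > a$band[2],
                            100 * pmax((a$mean_hi_zero - m) / (a$mean_hi_zero - a$band[2]), 0),
                            100))
  gv_sub <- 100 * (1 - pmin(daily$cv / a$cv_max, 1))
  tir_sub <- daily$rtir
  out <- daily
  out$gv_subscore <- gv_sub
  out$tir_subscore <- tir_sub
  out$mean_subscore <- mean_sub
  out$metscore <- weights[[1]] * gv_sub + weights[[2]] * tir_sub +
    weights[[3]] * mean_sub
  attr(out, "metscore_weights") <- weights
  attr(out, "metscore_anchors") <- a
  out
}

#' Per-subject mean metabolic score
#'
#' @param scored output of [compute_metscore].
#' @return Data frame with one row per subject: `subject_id`, `cohort`,
#'   `mean_metscore`, `n_days`.
#' @export
metscore_by_subject <- function(scored) {
  ok <- !is.na(scored$metscore)
  agg <- aggregate(scored$metscore[ok],
                   by = list(subject_id = scored$subject_id[ok],
                             cohort = scored$cohort[ok]),
                   FUN = mean)
  names(agg)[3] <- "mean_metscore"
  n <- aggregate(scored$metscore[ok],
                 by = list(subject_id = scored$subject_id[ok]),
                 FUN = length)
  agg$n_days <- n$x[match(agg$subject_id, n$Group.1)]
  agg[order(agg$subject_id), ]
}
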