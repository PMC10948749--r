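# Cohort statistics stage: outlier rules, normality-gated correlation,
# two-way group x day comparison with least-squares means, baseline-adjusted
# endpoint comparison, and ROC separation.

#' Remove outliers by the distribution-appropriate rule
#'
#' One pass only. Normal mode drops values outside mean +/- 3 SD;
#' nonparametric mode drops values below `Q1 - 3 IQR` or above `Q3 + 3 IQR`
#' (quartiles by linear-interpolation, type-7). With fewer than 4 values the
#' vector is passed through with a warning.
#'
#' @param values numeric vector (NAs ignored and retained in the count of
#'   removals as 0).
#' @param distribution `"normal"` or `"nonparametric"`.
#' @return List with `values` (kept), `n_removed` and `removed`.
#' @export
remove_outliers <- function(values, distribution = c("normal", "nonparametric")) {
  distribution <- match.arg(distribution)
  x <- values[!is.na(values)]
  if (length(x) < 4) {
    warning("fewer than 4 values; returning input unchanged")
    return(list(values = x, n_removed = 0L, removed = numeric(0)))
  }
  if (distribution == "normal") {
    mu <- mean(x); s <- sd(x)
    keep <- s == 0 | abs(x - mu) <= 3 * s
  } else {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- x >= q[1] - 3 * iqr & x <= q[2] + 3 * iqr
  }
  list(values = x[keep], n_removed = sum(!keep), removed = x[!keep])
}

#' Normality-gated correlation
#'
#' Applies a Shapiro-Wilk normality gate (alpha = 0.05) to each variable:
#' Pearson correlation when both pass, Spearman otherwise, mirroring common
#' biomarker-table practice. Two-sided p-value.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @param alpha gate level (default 0.05).
#' @return A one-row data frame of class `cgm_correlation`: `method`
#'   (`"pearson"`/`"spearman"`), `r`, `p_value`, `n_used`; `r` is `NA` when
#'   either vector has zero variance.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- data.frame(method = NA_character_, r = NA_real_, p_value = NA_real_,
                      n_used = n, stringsAsFactors = FALSE)
    class(out) <- c("cgm_correlation", "data.frame")
    return(out)
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }
  method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  out <- data.frame(method = method, r = unname(ct$estimate),
                    p_value = ct$p.value, n_used = n, stringsAsFactors = FALSE)
  class(out) <- c("cgm_correlation", "data.frame")
  out
}

#' Two-way cohort x day endpoint comparison
#'
#' Fits `value ~ cohort * day` with day as a categorical fixed effect
#' (complete-case), reports type-II main-effect and interaction p-values,
#' and per-day least-squares means with 95% confidence intervals per cohort.
#'
#' @param data data frame with columns `cohort`, `day_index` and the
#'   endpoint column named by `endpoint`.
#' @param endpoint name of the endpoint column.
#' @param lsm compute per-day least-squares means (default TRUE; turn off in
#'   large simulation loops).
#' @return A `cgm_group_comparison` list: `endpoint`, `p_cohort`, `p_day`,
#'   `p_interaction`, `lsm` (data frame cohort x day with `lsmean`,
#'   `lower`, `upper`).
#' @export
compare_groups_over_days <- function(data, endpoint, lsm = TRUE) {
  df <- data.frame(cohort = factor(data$cohort),
                   day = factor(data$day_index),
                   value = data[[endpoint]])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$cohort)) < 2) stop("need two cohorts")
  if (nlevels(droplevels(df$day)) < 2) stop("need at least 2 days")
  fit <- lm(value ~ cohort * day, data = df)
  an <- car::Anova(fit, type = 2)
  p <- an[["Pr(>F)"]]
  rn <- rownames(an)
  res <- list(endpoint = endpoint,
              p_cohort = p[rn == "cohort"],
              p_day = p[rn == "day"],
              p_interaction = p[rn == "cohort:day"],
              fit = fit)
  if (lsm) {
    em <- emmeans::emmeans(fit, ~ cohort | day)
    es <- as.data.frame(em)
    res$lsm <- data.frame(cohort = es$cohort,
                          day_index = as.integer(as.character(es$day)),
                          lsmean = es$emmean, lower = es$lower.CL,
                          upper = es$upper.CL, stringsAsFactors = FALSE)
  }
  class(res) <- "cgm_group_comparison"
  res
}

#' @export
print.cgm_group_comparison <- function(x, ...) {
  cat(sprintf("<cgm_group_comparison> endpoint: %s\n", x$endpoint))
  cat(sprintf("  cohort p = %.4g; day p = %.4g; cohort x day p = %.4g\n",
              x$p_cohort, x$p_day, x$p_interaction))
  invisible(x)
}

#' Baseline-adjusted endpoint comparison (ANCOVA)
#'
#' Fits `end ~ cohort + baseline` and reports the adjusted cohort effect
#' with 95% CI and p-value. With a constant baseline covariate the model
#' degenerates; the function falls back to the unadjusted two-group
#' comparison with a warning.
#'
#' @param end_values,baseline_values numeric vectors.
#' @param cohort cohort labels (two levels).
#' @return List: `effect` (adjusted difference, second level minus first),
#'   `ci` (length 2), `p_value`, `adjusted` (logical), `fit`.
#' @export
ancova_endpoint <- function(end_values, baseline_values, cohort) {
  df <- data.frame(end = end_values, base = baseline_values,
                   cohort = factor(cohort))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$cohort)) != 2) stop("need exactly two cohorts")
  adjusted <- sd(df$base) > 0
  if (!adjusted) {
    warning("constant baseline; falling back to unadjusted comparison")
    fit <- lm(end ~ cohort, data = df)
  } else {
    fit <- lm(end ~ cohort + base, data = df)
  }
  co <- grep("^cohort", names(coef(fit)), value = TRUE)
  ci <- confint(fit)[co, ]
  list(effect = unname(coef(fit)[co]),
       ci = unname(ci),
       p_value = summary(fit)$coefficients[co, "Pr(>|t|)"],
       adjusted = adjusted, fit = fit)
}

#' ROC separation of cohorts by an index
#'
#' Empirical ROC of classifying pre-diabetic subjects by an index value,
#' with trapezoidal AUC. Orientation is fixed so that when the index's
#' pre-diabetic mean is the higher one, higher values predict pre-diabetes
#' (AUC >= 0.5 for a well-ordered index).
#'
#' @param values numeric index values, one per subject.
#' @param cohort cohort labels (`"healthy"` / `"prediabetic"`).
#' @return List: `auc`, `direction`, `curve` (data frame with `threshold`,
#'   `sensitivity`, `specificity`), `roc` (the underlying `pROC::roc`).
#' @export
roc_separation <- function(values, cohort) {
  cohort <- as.character(cohort)
  ok <- !is.na(values) & !is.na(cohort)
  values <- values[ok]; cohort <- cohort[ok]
  if (!all(c("healthy", "prediabetic") %in% cohort)) {
    stop("both cohorts must be represented")
  }
  mh <- mean(values[cohort == "healthy"])
  mp <- mean(values[cohort == "prediabetic"])
  direction <- if (mp >= mh) "<" else ">" # pROC: "<" means control < case
  r <- pROC::roc(response = factor(cohort, levels = c("healthy", "prediabetic")),
                 predictor = values, direction = direction,
                 levels = c("healthy", "prediabetic"), quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)), direction = direction,
       curve = data.frame(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities),
       roc = r)
}

#' Correlation grid between GV indices and biomarkers
#'
#' Builds the long-format correlation table (index x biomarker x cohort)
#' used for the secondary-outcome analyses: each cell is a normality-gated
#' [correlate] result.
#'
#' @param summaries a [subject_summaries] table (or any per-subject frame
#'   with a `cohort` column).
#' @param panel per-subject table to correlate against, keyed by
#'   `subject_id`.
#' @param index_cols columns of `summaries` to use.
#' @param marker_cols columns of `panel` to use.
#' @param adjust optional p-value adjustment method (e.g. `"BH"`); default
#'   `"none"`, matching per-cell presentation.
#' @return Data frame: `index`, `marker`, `cohort`, `method`, `r`,
#'   `p_value`, `n_used` (plus `p_adj` when `adjust != "none"`).
#' @export
correlation_grid <- function(summaries, panel,
                             index_cols = c("mean_j_index", "mean_lbgi",
                                            "mean_hbgi", "adrr", "mean_mage",
                                            "modd", "mean_conga_n"),
                             marker_cols = c("hba1c", "ogtt_2h", "homa_ir"),
                             adjust = "none") {
  merged <- merge(summaries, panel, by = c("subject_id", "cohort"))
  missing_cols <- setdiff(c(index_cols, marker_cols), names(merged))
  if (length(missing_cols)) {
    stop("column(s) not found after merge: ", paste(missing_cols, collapse = ", "))
  }
  rows <- list()
  for (co in unique(merged$cohort)) {
    sub <- merged[merged$cohort == co, , drop = FALSE]
    for (ix in index_cols) for (mk in marker_cols) {
      cr <- correlate(sub[[ix]], sub[[mk]])
      rows[[length(rows) + 1]] <- data.frame(
        index = ix, marker = mk, cohort = co, method = cr$method,
        r = cr$r, p_value = cr$p_value, n_used = cr$n_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p_value, method = adjust)
  out
}
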