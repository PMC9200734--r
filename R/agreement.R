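#' Paired measurement series
#'
#' Two equal-length series of the same quantity (two methods, two sessions,
#' or two examiners). Rows with a missing entry in either series are dropped
#' with a message.
#'
#' @param values_x,values_y Numeric vectors of equal length.
#' @param label_x,label_y Names of the two series.
#' @return An object of class `paired_series`.
#' @export
paired_series <- function(values_x, values_y, label_x = "x", label_y = "y") {
  if (length(values_x) != length(values_y)) {
    abort_validation("values_x and values_y must have the same length")
  }
  keep <- stats::complete.cases(values_x, values_y)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("paired_series: dropped %d incomplete pair(s)", dropped))
  }
  x <- as.numeric(values_x[keep])
  y <- as.numeric(values_y[keep])
  if (length(x) < 2L) abort_validation("need at least 2 complete pairs")
  structure(
    list(values_x = x, values_y = y, label_x = label_x, label_y = label_y,
         n_dropped = dropped),
    class = "paired_series"
  )
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias), 95% limits of agreement (bias +/- 1.96 SD of the
#' differences, the conventional multiplier rather than a small-sample t
#' version), proportional-bias slope from regressing the differences on the
#' pair means (requires n >= 3), and a paired t-test p-value for bias != 0.
#' Differences are `y - x`.
#'
#' @param p A [paired_series()].
#' @return A list of class `bland_altman` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `prop_bias_slope`, `prop_bias_p`, `p_value`, `n`.
#' @export
bland_altman <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  d <- p$values_y - p$values_x
  m <- (p$values_y + p$values_x) / 2
  n <- length(d)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  slope <- NA_real_
  slope_p <- NA_real_
  if (n >= 3L && stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    # summary.lm warns on an exact fit (all differences equal); that is a
    # legitimate degenerate input here
    slope_p <- suppressWarnings(summary(fit)$coefficients[2, 4])
  }
  p_value <- if (sd_d > 0) {
    tt <- bias / (sd_d / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1)
  } else if (bias == 0) {
    NA_real_
  } else {
    0
  }
  structure(
    list(bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         prop_bias_slope = slope, prop_bias_p = slope_p,
         p_value = p_value, n = n,
         label_x = p$label_x, label_y = p$label_y),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %s vs %s (n = %d)\n", x$label_y, x$label_x, x$n))
  cat(sprintf("  bias %.2f, 95%% LOA [%.2f, %.2f]\n",
              x$bias, x$loa_low, x$loa_high))
  if (!is.na(x$prop_bias_slope)) {
    cat(sprintf("  proportional-bias slope %.3f (p = %.3g)\n",
                x$prop_bias_slope, x$prop_bias_p))
  }
  if (!is.na(x$p_value)) cat(sprintf("  paired t p = %.3g\n", x$p_value))
  invisible(x)
}

#' Coefficient of variation of paired measurements
#'
#' Two common conventions are offered because the literature rarely states
#' which is used: `"sd_diff"` (default) is 100 * SD(differences) / grand
#' mean; `"within_subject"` divides the SD of differences by sqrt(2) first.
#' The convention used is recorded in the result.
#'
#' @param p A [paired_series()].
#' @param convention `"sd_diff"` or `"within_subject"`.
#' @return A list with `cv_percent` and `convention`.
#' @export
cv_percent <- function(p, convention = c("sd_diff", "within_subject")) {
  stopifnot(inherits(p, "paired_series"))
  convention <- match.arg(convention)
  gm <- mean(c(p$values_x, p$values_y))
  if (gm <= 0) abort_domain("grand mean must be > 0 for a coefficient of variation")
  sd_d <- stats::sd(p$values_y - p$values_x)
  cv <- switch(convention,
               sd_diff = 100 * sd_d / gm,
               within_subject = 100 * (sd_d / sqrt(2)) / gm)
  list(cv_percent = cv, convention = convention)
}

#' Intraclass correlation coefficient
#'
#' Default form ICC(2,1): two-way random effects, absolute agreement, single
#' measures, computed from the classical ANOVA mean squares
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}.}
#' With zero total variance the coefficient is undefined and a flagged
#' result (`value = NA`) is returned.
#'
#' @param p A [paired_series()] (the two series are the two "raters").
#' @param form Currently only `"ICC(2,1)"`.
#' @return A list with `value`, `form`, `n`, `k`, and `defined`.
#' @export
icc <- function(p, form = "ICC(2,1)") {
  stopifnot(inherits(p, "paired_series"))
  if (!identical(form, "ICC(2,1)")) {
    abort_config("only form 'ICC(2,1)' is implemented")
  }
  m <- cbind(p$values_x, p$values_y)
  n <- nrow(m)
  if (n < 3L) abort_validation("ICC requires at least 3 pairs")
  k <- ncol(m)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) {
    return(list(value = NA_real_, form = form, n = n, k = k, defined = FALSE))
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  value <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(value = value, form = form, n = n, k = k, defined = TRUE)
}

#' Built-in indexed-mass hypertrophy cutoffs
#'
#' The cutoff table (g/m^2, indexed to body surface area) stratified by
#' method group, sex and age. Three groups are distinguished:
#' `cmr_based` (used for the disc-expansion, biplane and 3D methods;
#' age-stratified), `ase_te_al` (truncated ellipsoid and area-length) and
#' `ase_dev` (cube formula). Shipped as an editable CSV in
#' `inst/extdata/hypertrophy_cutoffs.csv`.
#'
#' @param path Optional path to an alternative cutoff CSV with columns
#'   `group`, `sex`, `age_min`, `age_max`, `threshold_g_m2`.
#' @return A data frame of class `cutoff_table`.
#' @export
default_cutoffs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hypertrophy_cutoffs.csv",
                        package = "echolvm", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "sex", "age_min", "age_max", "threshold_g_m2")
  if (!all(need %in% names(df))) {
    abort_config("cutoff table must have columns group, sex, age_min, age_max, threshold_g_m2")
  }
  df$age_min <- as.numeric(df$age_min)
  df$age_max <- as.numeric(df$age_max)
  if (any(df$threshold_g_m2 <= 0)) abort_config("cutoff thresholds must be > 0")
  class(df) <- c("cutoff_table", "data.frame")
  df
}

#' Indexed end-diastolic-volume dilatation cutoffs
#'
#' Companion table (ml/m^2) for classifying LV dilatation from indexed EDV,
#' age- and sex-stratified, shipped as
#' `inst/extdata/dilatation_cutoffs.csv`. Use with [classify_indexed()].
#'
#' @return A data frame of class `cutoff_table` (thresholds in ml/m^2 under
#'   the same `threshold_g_m2` column name used by [classify_indexed()]).
#' @export
default_dilatation_cutoffs <- function() {
  default_cutoffs(system.file("extdata", "dilatation_cutoffs.csv",
                              package = "echolvm", mustWork = TRUE))
}

.method_cutoff_group <- function(method) {
  switch(method,
         NOVEL = , BP = , X3DE = "cmr_based",
         TE = , AL = "ase_te_al",
         DEV = "ase_dev",
         abort_config(sprintf("no cutoff group for method '%s'", method)))
}

#' Classify an indexed value against a cutoff table
#'
#' @param indexed_value Indexed measurement (e.g. g/m^2).
#' @param subj A [subject()].
#' @param group Cutoff group name present in `cuts$group`.
#' @param cuts A `cutoff_table`.
#' @return `TRUE` when `indexed_value >= threshold` for the subject's
#'   sex/age stratum.
#' @export
classify_indexed <- function(indexed_value, subj, group, cuts) {
  stopifnot(inherits(subj, "subject"), inherits(cuts, "cutoff_table"))
  check_number(indexed_value, "indexed_value", min = 0)
  hit <- cuts$group == group & cuts$sex == subj$sex &
    subj$age_years >= cuts$age_min & subj$age_years < cuts$age_max
  if (sum(hit) != 1L) {
    abort_config(sprintf(
      "cutoff table has %d rows for group '%s', sex %s, age %g (need exactly 1)",
      sum(hit), group, subj$sex, subj$age_years
    ))
  }
  indexed_value >= cuts$threshold_g_m2[hit]
}

#' Classify left-ventricular hypertrophy
#'
#' Indexes the mass to body surface area and compares against the
#' method-appropriate sex/age stratum of the cutoff table.
#'
#' @param lvm_g LV mass in g.
#' @param subj A [subject()].
#' @param method Method id (`"NOVEL"`, `"BP"`, `"X3DE"`, `"TE"`, `"AL"`,
#'   `"DEV"`) selecting the cutoff group.
#' @param cuts A `cutoff_table`, default [default_cutoffs()].
#' @return `TRUE` for hypertrophy (indexed mass at or above the threshold).
#' @examples
#' s <- subject("p1", 45, "M", 2.0)
#' classify_hypertrophy(200, s, "NOVEL") # 100 g/m2 >= 92 -> TRUE
#' @export
classify_hypertrophy <- function(lvm_g, subj, method, cuts = default_cutoffs()) {
  check_number(lvm_g, "lvm_g", min = 0)
  classify_indexed(lvm_g / subj$bsa_m2, subj, .method_cutoff_group(method),
                   cuts)
}

#' Diagnostic performance of a binary classifier
#'
#' Standard 2x2 proportions in percent. When a denominator class is empty
#' the corresponding entry is `NA` (flagged undefined) with a warning.
#'
#' @param pred,truth Logical vectors of equal length.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`
#'   (each in `[0, 100]` or `NA`).
#' @export
diagnostic_performance <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort_validation("pred and truth must have the same length")
  }
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  pct <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: empty denominator", what), call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  c(sensitivity = pct(tp, tp + fn, "sensitivity"),
    specificity = pct(tn, tn + fp, "specificity"),
    ppv = pct(tp, tp + fp, "PPV"),
    npv = pct(tn, tn + fn, "NPV"))
}
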