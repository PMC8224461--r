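#' Bland-Altman repeatability analysis of trial ensembles
#'
#' For each sample the per-trial difference from the sample mean (or, with
#' `bias_variant = "leave_one_out"`, from the mean of the remaining trials)
#' is plotted against the sample mean. The bias is the grand mean of the
#' differences and the limits of agreement are `bias +/- 1.96 SD` of the
#' differences (sample SD, n - 1). With `normalized = TRUE` each difference
#' is divided by its sample mean and expressed in percent.
#'
#' Note that under the `"from_sample_mean"` definition the differences within
#' each sample sum to zero, so the bias is identically zero by construction;
#' `"leave_one_out"` removes that constraint.
#'
#' @param ensembles A list of [trial_ensemble()] objects (bare numeric
#'   vectors of speeds are accepted and wrapped).
#' @param normalized Express differences as percent of the sample mean.
#' @param bias_variant `"from_sample_mean"` (default) or `"leave_one_out"`.
#' @return A `bland_altman_result`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_differences` (m/s, or percent when normalized), `points` (data frame
#'   with sample, mean, difference), `normalized`.
#' @export
bland_altman <- function(ensembles, normalized = FALSE,
                         bias_variant = c("from_sample_mean", "leave_one_out")) {
  bias_variant <- match.arg(bias_variant)
  if (inherits(ensembles, "trial_ensemble")) ensembles <- list(ensembles)
  ensembles <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    if (inherits(e, "trial_ensemble")) e else trial_ensemble(paste0("s", i), e)
  })
  pts <- do.call(rbind, lapply(ensembles, function(e) {
    s <- e$trials
    k <- length(s)
    if (k < 2) stop("every ensemble needs at least 2 trials")
    m <- mean(s)
    diffs <- if (bias_variant == "from_sample_mean") s - m
    else s - (sum(s) - s) / (k - 1)
    if (normalized) {
      if (m <= 0) stop("normalization requires positive sample means")
      diffs <- diffs / m * 100
    }
    data.frame(sample = e$sample_id, mean = m, difference = diffs,
               stringsAsFactors = FALSE)
  }))
  bias <- mean(pts$difference)
  sd_d <- stats::sd(pts$difference)
  structure(list(bias = bias,
                 loa_upper = bias + 1.96 * sd_d,
                 loa_lower = bias - 1.96 * sd_d,
                 sd_differences = sd_d,
                 points = pts,
                 normalized = normalized,
                 bias_variant = bias_variant),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  un <- if (x$normalized) "%" else "m/s"
  cat(sprintf("Bland-Altman (%s): bias %.4g %s, LOA [%.4g, %.4g] %s (%d points)\n",
              x$bias_variant, x$bias, un, x$loa_lower, x$loa_upper, un,
              nrow(x$points)))
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the two-way ANOVA mean squares of a subjects-by-measurements matrix:
#' `ICC(2,1) = (MS_R - MS_E) / (MS_R + (k - 1) MS_E + k (MS_C - MS_E) / n)`
#' with `n` subjects, `k` repeated measurements, `MS_R` the between-subject,
#' `MS_C` the between-measurement and `MS_E` the residual mean square.
#'
#' @param mat Numeric matrix, subjects in rows, repeated measurements in
#'   columns; >= 2 of each, no missing cells.
#' @return An `icc_result`: `icc`, `model_label`, and `variance_components`
#'   (between_subject, between_rater, residual, plus the mean squares).
#' @export
icc <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("ICC needs >= 2 subjects and >= 2 measurements")
  if (any(!is.finite(mat))) stop("ICC requires a complete matrix")
  if (stats::var(as.vector(mat)) == 0) {
    warning("zero total variance: ICC defined as 1 (degenerate perfect agreement)")
    return(structure(list(icc = 1,
                          model_label = "ICC(2,1) two-way random, absolute agreement",
                          variance_components = list(between_subject = 0,
                                                     between_rater = 0,
                                                     residual = 0,
                                                     ms_rows = 0, ms_cols = 0,
                                                     ms_error = 0)),
                     class = "icc_result"))
  }
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  aov_tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- aov_tab["subject", "Mean Sq"]
  msc <- aov_tab["rater", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc21,
                 model_label = "ICC(2,1) two-way random, absolute agreement",
                 variance_components = list(
                   between_subject = (msr - mse) / k,
                   between_rater = (msc - mse) / n,
                   residual = mse,
                   ms_rows = msr, ms_cols = msc, ms_error = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: %.4f\n", x$model_label, x$icc))
  invisible(x)
}

#' Mean absolute percent error against a reference
#'
#' `mean(|measured - reference| / reference) * 100`, the accuracy metric for
#' comparing elastography moduli with the uniaxial-compression reference.
#'
#' @param measured Numeric vector of measurements.
#' @param reference Numeric vector of reference values (> 0), same length.
#' @return MAPE in percent.
#' @export
mape <- function(measured, reference) {
  if (length(measured) != length(reference)) stop("length mismatch")
  if (any(reference <= 0)) stop("reference values must be positive")
  mean(abs(measured - reference) / reference) * 100
}

#' Linear trend fit on Bland-Altman points
#'
#' Ordinary least squares of difference on mean, with the two-sided t-test
#' of zero slope, used to check for speed-dependent bias on a Bland-Altman
#' plot.
#'
#' @param points Data frame (or `bland_altman_result`) with columns `mean`
#'   and `difference`; >= 3 points with non-degenerate means.
#' @return A `trend_fit_result`: `slope`, `slope_se`, `p_value`.
#' @export
trend_fit <- function(points) {
  if (inherits(points, "bland_altman_result")) points <- points$points
  x <- points$mean
  y <- points$difference
  if (length(x) < 3) stop("trend fit needs at least 3 points")
  if (stats::var(x) == 0) stop("degenerate x: all means equal")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate inputs
  slope <- stats::coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  if (se == 0) {
    # zero residual variance: exact line (p -> 0) or all-zero differences (p = 1)
    p <- if (abs(slope) > 0) 0 else 1
  } else {
    p <- sm$coefficients["x", "Pr(>|t|)"]
  }
  structure(list(slope = slope, slope_se = se, p_value = p),
            class = "trend_fit_result")
}
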