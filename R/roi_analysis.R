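#' Summarize a parameter map over an ROI
#'
#' Mean and SD (n-1 denominator) over masked, non-NaN voxels; `n_failed`
#' counts masked voxels that failed to fit.
#'
#' @param map A [parameter_map()].
#' @param mask A [roi_mask()] on the same grid.
#' @param subject_id Subject identifier carried into the summary.
#' @return A one-row `data.frame` with columns `subject_id`,
#'   `parameter_name`, `mean`, `sd`, `n_voxels`, `n_failed`.
#' @export
roi_summary <- function(map, mask, subject_id = "subject") {
  stopifnot(inherits(map, "parameter_map"), inherits(mask, "roi_mask"))
  if (!identical(dim(map$values), dim(mask$mask)))
    stop("map and mask grids differ", call. = FALSE)
  v <- map$values[mask$mask]
  ok <- !is.nan(v) & !is.na(v)
  if (!any(ok))
    stop(sprintf("all masked voxels NaN for subject '%s', parameter '%s'",
                 subject_id, map$parameter_name), call. = FALSE)
  data.frame(subject_id = subject_id,
             parameter_name = map$parameter_name,
             mean = mean(v[ok]),
             sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
             n_voxels = sum(ok),
             n_failed = sum(!ok),
             stringsAsFactors = FALSE)
}

#' Intraclass correlation coefficient for reader agreement
#'
#' Computes single-measurement ICCs from the two-way ANOVA decomposition of a
#' complete subjects-by-raters matrix, with 95% confidence intervals from the
#' standard F-distribution method:
#' \describe{
#'   \item{`two_way_random_absolute`}{ICC(2,1): raters random, absolute
#'     agreement — systematic rater offsets count against agreement. The
#'     conventional inter-reader form.}
#'   \item{`two_way_mixed_consistency`}{ICC(3,1): raters fixed, consistency —
#'     a constant offset between reads does not reduce agreement. The
#'     conventional intra-reader form.}
#' }
#' ICC is invariant to adding a common constant to all ratings and to
#' rescaling all ratings by a positive factor. Whenever the between-rater
#' mean square is at least the error mean square (i.e. systematic rater
#' offsets are not smaller than noise), the absolute-agreement form does not
#' exceed the consistency form on the same data.
#'
#' @param ratings Numeric matrix, subjects in rows, raters (or reads) in
#'   columns; no missing cells (>= 5 subjects, >= 2 raters).
#' @param model `"two_way_random_absolute"` or `"two_way_mixed_consistency"`.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`, `model`,
#'   `n_subjects`, `n_raters`, and the ANOVA mean squares.
#' @export
icc <- function(ratings,
                model = c("two_way_random_absolute", "two_way_mixed_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells in ratings matrix", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need >= 5 subjects", call. = FALSE)
  if (k < 2L) stop("need >= 2 raters", call. = FALSE)

  row_m <- rowMeans(ratings); col_m <- colMeans(ratings); grand <- mean(ratings)
  ssr <- k * sum((row_m - grand)^2)          # between-subject
  ssc <- n * sum((col_m - grand)^2)          # between-rater
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))

  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    warning("zero between-subject variance: ICC undefined")
    return(structure(list(icc = NaN, ci_low = NaN, ci_high = NaN,
                          model = model, n_subjects = n, n_raters = k,
                          msr = msr, msc = msc, mse = mse),
                     class = "icc_result"))
  }

  alpha <- 1 - conf_level
  if (model == "two_way_mixed_consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fv <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- fv / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- fv * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Satterthwaite df for the absolute-agreement interval (McGraw & Wong)
    fj <- msc / mse
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- ((a * fj + b)^2) /
      ((a^2 * fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
                 model = model, n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC [%s]: %.3f (95%% CI %.3f-%.3f), %d subjects x %d raters — %s consistency\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$n_subjects, x$n_raters,
              classify_icc(x$icc)))
  invisible(x)
}

#' Classify an ICC value
#'
#' Agreement bands: >= 0.75 remarkable; 0.40 to < 0.75 medium; < 0.40 poor.
#'
#' @param icc Finite ICC value (or an `icc_result`).
#' @return `"remarkable"`, `"medium"` or `"poor"`.
#' @export
classify_icc <- function(icc) {
  if (inherits(icc, "icc_result")) icc <- icc$icc
  if (!is.finite(icc)) stop("ICC must be finite", call. = FALSE)
  if (icc >= 0.75) "remarkable" else if (icc >= 0.40) "medium" else "poor"
}
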