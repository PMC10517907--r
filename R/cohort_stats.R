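#' Compare a variable between outcome groups
#'
#' Continuous variables: Shapiro-Wilk normality gate per group at alpha =
#' 0.05; if both groups pass, Welch's t-test, otherwise the Mann-Whitney U
#' test. Categorical variables: Pearson chi-square; Yates continuity
#' correction is applied to 2x2 tables by default.
#'
#' @param cohort A `cohort_table` (see [as_cohort_table()]).
#' @param variable Column name to compare between `adverse` and
#'   `non_adverse`.
#' @param yates Apply the continuity correction to 2x2 contingency tables.
#' @param normality_alpha Significance level of the Shapiro-Wilk gate.
#' @return Object of class `group_comparison`: test used, statistic, p-value,
#'   and per-group summaries (mean/sd for continuous, counts for
#'   categorical).
#' @export
compare_groups <- function(cohort, variable, yates = TRUE,
                           normality_alpha = 0.05) {
  if (!variable %in% names(cohort))
    stop("variable '", variable, "' not in cohort table", call. = FALSE)
  g <- factor(cohort$group, levels = c("adverse", "non_adverse"))
  x <- cohort[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  if (any(table(g) == 0L)) stop("a group is empty", call. = FALSE)

  if (is.numeric(x)) {
    if (any(table(g) < 2L))
      stop("need >= 2 observations per group", call. = FALSE)
    xs <- split(x, g)
    normal <- vapply(xs, function(v)
      stats::sd(v) > 0 && stats::shapiro.test(v)$p.value > normality_alpha,
      logical(1))
    if (all(normal)) {
      ht <- stats::t.test(x ~ g)
      test <- "t"
    } else {
      ht <- stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE)
      test <- "mann_whitney"
    }
    res <- list(parameter = variable, test = test,
                statistic = unname(ht$statistic), p = ht$p.value,
                continuity_correction = FALSE,
                mean_sd_by_group = lapply(xs, function(v)
                  c(mean = mean(v), sd = stats::sd(v))))
  } else {
    tab <- table(g, factor(x))
    correct <- yates && all(dim(tab) == c(2L, 2L))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res <- list(parameter = variable, test = "chi_square",
                statistic = unname(ht$statistic), p = ht$p.value,
                continuity_correction = correct,
                counts = tab)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, statistic = %.4g, p = %.4g%s\n", x$parameter,
              x$test, x$statistic, x$p,
              if (isTRUE(x$continuity_correction)) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Convenience wrapper used for categorical clinical covariates given as
#' counts rather than subject rows.
#'
#' @param counts 2x2 matrix of counts (groups in rows).
#' @param yates Apply the Yates continuity correction.
#' @return `htest` object from [stats::chisq.test()].
#' @export
chi_square_2x2 <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  stats::chisq.test(counts, correct = yates)
}

#' Multivariable logistic risk model
#'
#' Maximum-likelihood logistic regression of adverse outcome on the given
#' covariates, with Wald confidence intervals and per-term odds ratios
#' (`OR = exp(coefficient)`). Complete or quasi-complete separation is
#' detected (fitted probabilities numerically 0 or 1) and flagged; the
#' coefficients of the last stable iterate are still reported.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Character vector of numeric covariate columns.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `logistic_model_result` with a `terms` data frame
#'   (`name`, `coefficient`, `odds_ratio`, `ci_low`, `ci_high`, `p`),
#'   `converged`, `separation_flag`, and the underlying `glm` fit.
#' @export
logistic_model <- function(cohort, covariates, conf_level = 0.95) {
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov))
    stop("covariate(s) not in cohort: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) < 10L) stop("need >= 10 subjects", call. = FALSE)
  y <- as.integer(cohort$group == "adverse")
  dat <- data.frame(.y = y, cohort[covariates], check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                                collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # quasi-complete separation can stop short of the glm warning: an extreme
  # linear predictor is the same symptom
  if (any(abs(stats::predict(fit, type = "link")) > 15)) separation <- TRUE
  if (!fit$converged && !separation)
    stop("logistic model failed to converge (deviance ", round(fit$deviance, 3),
         ")", call. = FALSE)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    name = rownames(sm),
    coefficient = sm[, "Estimate"],
    odds_ratio = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p = sm[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, converged = fit$converged,
                 separation_flag = separation, fit = fit),
            class = "logistic_model_result")
}

#' @export
print.logistic_model_result <- function(x, ...) {
  cat("logistic risk model",
      if (x$separation_flag) "(SEPARATION detected)" else "", "\n")
  tt <- x$terms
  tt[-1] <- lapply(tt[-1], signif, 4)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Backward-eliminated risk model from univariately significant parameters
#'
#' Screening step: each candidate parameter is compared between groups with
#' [compare_groups()]; parameters with p below `enter_alpha` enter a joint
#' logistic model, which is then reduced by backward elimination on the Wald
#' p-value until all remaining terms have p below `stay_alpha`.
#'
#' @param cohort A `cohort_table`.
#' @param candidates Candidate parameter columns.
#' @param enter_alpha Univariate significance level to enter the model.
#' @param stay_alpha Wald significance level to stay in the model.
#' @return A list: `selected` (final covariates), `model`
#'   (`logistic_model_result`), `univariate` (screening p-values).
#' @export
select_risk_model <- function(cohort, candidates = c("mu_diff", "f", "D",
                                                     "Dstar", "DDC", "Alpha",
                                                     "ADC"),
                              enter_alpha = 0.05, stay_alpha = 0.05) {
  candidates <- intersect(candidates, names(cohort))
  uni <- vapply(candidates, function(p) compare_groups(cohort, p)$p, 1.0)
  current <- candidates[uni < enter_alpha]
  if (!length(current))
    return(list(selected = character(), model = NULL, univariate = uni))
  repeat {
    m <- logistic_model(cohort, current)
    pv <- m$terms$p[-1]                 # drop intercept
    if (length(current) == 1L || max(pv) < stay_alpha) break
    current <- current[-which.max(pv)]
  }
  list(selected = current, model = m, univariate = uni)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical (trapezoidal) ROC of a per-subject score against a binary
#' outcome. By default the orientation is chosen automatically so AUC >= 0.5;
#' it can be fixed with `direction`. The 95% CI uses the DeLong method (a
#' seeded stratified bootstrap is available). The cutoff maximizes the Youden
#' index J = sensitivity + specificity - 1, ties broken toward higher
#' specificity. Constant scores return AUC = 0.5 with an undefined cutoff and
#' a degenerate flag.
#'
#' @param scores Numeric per-subject scores.
#' @param labels Binary outcome: logical, 0/1, or `adverse`/`non_adverse`.
#' @param direction `"auto"`, `"higher_is_positive"`, or
#'   `"lower_is_positive"`.
#' @param ci_method `"delong"` or `"bootstrap"` (2000 stratified resamples).
#' @param boot_seed Seed used when `ci_method = "bootstrap"`.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `direction`, `degenerate`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("auto", "higher_is_positive",
                                       "lower_is_positive"),
                         ci_method = c("delong", "bootstrap"),
                         boot_seed = 1L) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  y <- to_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (length(scores) != length(y))
    stop("scores and labels differ in length", call. = FALSE)
  if (stats::sd(scores) == 0) {
    return(structure(list(auc = 0.5, ci_low = NaN, ci_high = NaN,
                          cutoff = NaN, sensitivity = NaN, specificity = NaN,
                          direction = direction, degenerate = TRUE),
                     class = "roc_result"))
  }
  proc_dir <- switch(direction, auto = "auto",
                     higher_is_positive = "<",   # controls < cases
                     lower_is_positive = ">")
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = proc_dir, quiet = TRUE)
  ci <- if (ci_method == "delong")
    suppressWarnings(pROC::ci.auc(r, method = "delong"))
        else {
          set.seed(boot_seed)
          pROC::ci.auc(r, method = "bootstrap", boot.n = 2000,
                       boot.stratified = TRUE, progress = "none")
        }
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[order(-best$specificity), , drop = FALSE][1, ]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 cutoff = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 direction = if (direction == "auto")
                   if (r$direction == "<") "higher_is_positive"
                   else "lower_is_positive"
                 else direction,
                 degenerate = FALSE),
            class = "roc_result")
}

to_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  lv <- unique(as.character(labels))
  if (!all(lv %in% c("adverse", "non_adverse")))
    stop("labels must be binary or adverse/non_adverse", call. = FALSE)
  as.integer(labels == "adverse")
}

#' @export
print.roc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("ROC: degenerate (constant scores), AUC = 0.5\n")
    return(invisible(x))
  }
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), cutoff = %.4g (%s), sens = %.3f, spec = %.3f\n",
              x$auc, x$ci_low, x$ci_high, x$cutoff, x$direction,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Closed-form AUC of two normal score distributions
#'
#' `AUC = Phi(|m_pos - m_neg| / sqrt(s_pos^2 + s_neg^2))` — the binormal
#' oracle used to cross-check empirical AUCs from simulated cohorts.
#'
#' @param m_pos,s_pos Mean and SD of the positive-class scores.
#' @param m_neg,s_neg Mean and SD of the negative-class scores.
#' @return AUC in `[0.5, 1]`.
#' @export
binormal_auc <- function(m_pos, s_pos, m_neg, s_neg) {
  if (s_pos <= 0 || s_neg <= 0)
    stop("standard deviations must be positive", call. = FALSE)
  stats::pnorm(abs(m_pos - m_neg) / sqrt(s_pos^2 + s_neg^2))
}

#' Correlation of a parameter with gestational age
#'
#' @param cohort A `cohort_table` with a `ga_mri` column (weeks).
#' @param parameter Parameter column to correlate.
#' @param method `"pearson"` or `"spearman"`.
#' @param ga_column Gestational-age column name.
#' @return Object of class `correlation_result`: `r`, `p`, `method`, `n`.
#' @export
ga_correlation <- function(cohort, parameter,
                           method = c("pearson", "spearman"),
                           ga_column = "ga_mri") {
  method <- match.arg(method)
  for (col in c(parameter, ga_column))
    if (!col %in% names(cohort))
      stop("column '", col, "' not in cohort table", call. = FALSE)
  x <- cohort[[ga_column]]; y <- cohort[[parameter]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(r = unname(ct$estimate), p = ct$p.value, method = method,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}
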