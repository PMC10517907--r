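test_that("Yates-corrected chi-square reproduces the published covariate tests", {
  # preterm deliveries: 11/9 adverse vs 6/34 non-adverse
  preterm <- chi_square_2x2(matrix(c(11, 9, 6, 34), 2, byrow = TRUE))
  expect_equal(unname(preterm$statistic), 8.6286, tolerance = 1e-4)
  expect_equal(round(preterm$p.value, 3), 0.003)

  # delivery route: 4 vaginal / 16 cesarean vs 19 / 21
  route <- chi_square_2x2(matrix(c(4, 16, 19, 21), 2, byrow = TRUE))
  expect_equal(round(route$p.value, 3), 0.074)

  # neonatal sex: the published p matches the uncorrected statistic
  sex <- chi_square_2x2(matrix(c(6, 14, 16, 24), 2, byrow = TRUE),
                        yates = FALSE)
  expect_equal(sex$p.value, 0.4486, tolerance = 1e-3)
})

test_that("group comparison gates on normality and swaps tests accordingly", {
  set.seed(41)
  n <- 40
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("S%02d", 1:(2 * n)),
    group = rep(c("adverse", "non_adverse"), each = n),
    gauss = c(rnorm(n, 5, 1), rnorm(n, 6, 1)),
    skewed = exp(c(rnorm(n, 0, 1), rnorm(n, 0.8, 1))),
    cat = sample(c("yes", "no"), 2 * n, replace = TRUE)))
  expect_identical(compare_groups(cohort, "gauss")$test, "t")
  expect_identical(compare_groups(cohort, "skewed")$test, "mann_whitney")
  expect_identical(compare_groups(cohort, "cat")$test, "chi_square")
  expect_error(compare_groups(cohort, "nope"), "not in cohort")

  # two-sided p-values are invariant to swapping the group labels
  swapped <- cohort
  swapped$group <- ifelse(cohort$group == "adverse", "non_adverse", "adverse")
  for (v in c("gauss", "skewed", "cat"))
    expect_equal(compare_groups(swapped, v)$p, compare_groups(cohort, v)$p,
                 tolerance = 1e-12)

  same <- cohort; same$gauss <- rep(cohort$gauss[1:n], 2)
  res <- compare_groups(same, "gauss")
  expect_gt(res$p, 0.99)
})

test_that("logistic model recovers known coefficients at large n", {
  set.seed(42)
  n <- 40000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 0.5 + 1.0 * x1 - 0.7 * x2
  y <- rbinom(n, 1, plogis(eta))
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("S%05d", 1:n),
    group = ifelse(y == 1, "adverse", "non_adverse"),
    x1 = x1, x2 = x2))
  m <- logistic_model(cohort, c("x1", "x2"))
  expect_true(m$converged)
  expect_false(m$separation_flag)
  est <- m$terms$coefficient
  expect_lt(rel_err(est[2], 1.0), 0.05)
  expect_lt(rel_err(est[3], -0.7), 0.05)
  expect_equal(m$terms$odds_ratio, exp(m$terms$coefficient), tolerance = 1e-12)
})

test_that("separation is detected and covariate rescaling is equivariant", {
  set.seed(43)
  n <- 40
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("S%02d", 1:n),
    group = rep(c("adverse", "non_adverse"), each = n / 2),
    sep = rep(c(1, 0), each = n / 2) + rnorm(n, 0, 1e-4),
    x = rnorm(n)))
  m <- logistic_model(cohort, "sep")
  expect_true(m$separation_flag)

  set.seed(44)
  cohort2 <- as_cohort_table(data.frame(
    subject_id = sprintf("S%03d", 1:200),
    group = sample(c("adverse", "non_adverse"), 200, TRUE),
    x = rnorm(200)))
  cohort2$x10 <- cohort2$x * 10
  b1 <- logistic_model(cohort2, "x")$terms$coefficient[2]
  b10 <- logistic_model(cohort2, "x10")$terms$coefficient[2]
  expect_equal(b10, b1 / 10, tolerance = 1e-8)
})

test_that("backward elimination keeps only jointly significant parameters", {
  set.seed(45)
  n <- 150
  strong <- c(rnorm(n / 3, 7, 1), rnorm(2 * n / 3, 5, 1))
  noise <- rnorm(n)
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("S%03d", 1:n),
    group = rep(c("adverse", "non_adverse"), c(n / 3, 2 * n / 3)),
    mu_diff = strong, Alpha = noise))
  sel <- select_risk_model(cohort, c("mu_diff", "Alpha"))
  expect_identical(sel$selected, "mu_diff")
  expect_true(all(sel$model$terms$p[-1] < 0.05))
})

test_that("empirical AUC equals the Mann-Whitney rank statistic", {
  set.seed(46)
  for (i in 1:5) {
    n1 <- sample(10:30, 1); n0 <- sample(10:30, 1)
    pos <- rnorm(n1, 1, 1); neg <- rnorm(n0, 0, 1)
    scores <- c(pos, neg)
    labels <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(scores, labels, direction = "higher_is_positive")
    u <- unname(stats::wilcox.test(pos, neg, exact = FALSE)$statistic)
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-10)
    # AUC invariant under strictly increasing transforms of the scores
    r2 <- roc_analysis(exp(scores / 2), labels,
                       direction = "higher_is_positive")
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("ROC handles perfect separation, constant scores and orientation", {
  labels <- rep(c("adverse", "non_adverse"), c(5, 7))
  perfect <- c(rep(10, 5), rep(1, 7))
  r <- roc_analysis(perfect, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  flat <- roc_analysis(rep(2, 12), labels)
  expect_true(flat$degenerate)
  expect_equal(flat$auc, 0.5)
  expect_true(is.nan(flat$cutoff))

  # auto orientation never reports below chance
  set.seed(47)
  auto <- roc_analysis(rnorm(12), labels)
  expect_gte(auto$auc, 0.5)
  expect_error(roc_analysis(1:5, rep("adverse", 5)), "both outcome classes")
})

test_that("the combined logistic score dominates single parameters in AUC", {
  set.seed(48)
  reps <- 20
  wins <- vapply(seq_len(reps), function(i) {
    n1 <- 20; n0 <- 40
    x1 <- c(rnorm(n1, 1.0), rnorm(n0, 0))
    x2 <- c(rnorm(n1, 0.8), rnorm(n0, 0))
    g <- rep(c("adverse", "non_adverse"), c(n1, n0))
    cohort <- as_cohort_table(data.frame(
      subject_id = sprintf("S%02d", 1:(n1 + n0)), group = g,
      x1 = x1, x2 = x2))
    m <- logistic_model(cohort, c("x1", "x2"))
    combined <- stats::predict(m$fit, type = "link")
    auc_c <- roc_analysis(combined, g, direction = "higher_is_positive")$auc
    auc_1 <- roc_analysis(x1, g, direction = "higher_is_positive")$auc
    auc_2 <- roc_analysis(x2, g, direction = "higher_is_positive")$auc
    auc_c >= max(auc_1, auc_2) - 1e-9
  }, logical(1))
  # in-sample, the ML combination can only very rarely lose to a component
  expect_gte(mean(wins), 0.95)
})

test_that("binormal closed form matches arithmetic and large-sample simulation", {
  expect_equal(binormal_auc(1, 1, 1, 2), 0.5)
  # frozen normal-CDF arithmetic from the published group summaries
  expect_equal(binormal_auc(23.56, 3.94, 28.44, 5.98), 0.752204,
               tolerance = 1e-6)
  expect_equal(binormal_auc(5.47, 0.68, 4.89, 0.59), 0.740292,
               tolerance = 1e-6)
  expect_error(binormal_auc(1, 0, 0, 1), "positive")

  set.seed(49)
  pos <- rnorm(20000, 5.47, 0.68); neg <- rnorm(20000, 4.89, 0.59)
  emp <- roc_analysis(c(pos, neg), rep(c(1, 0), each = 20000),
                      direction = "higher_is_positive")$auc
  expect_equal(emp, binormal_auc(5.47, 0.68, 4.89, 0.59), tolerance = 0.01)
})

test_that("gestational-age correlation honors method choice and edge cases", {
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("S%02d", 1:20),
    group = rep(c("adverse", "non_adverse"), 10),
    ga_mri = seq(28, 38, length.out = 20)))
  cohort$lin <- 2 * cohort$ga_mri + 1
  cohort$cube <- (cohort$ga_mri - 33)^3
  expect_equal(ga_correlation(cohort, "lin", "pearson")$r, 1, tolerance = 1e-12)
  expect_equal(ga_correlation(cohort, "lin", "spearman")$r, 1)
  expect_equal(ga_correlation(cohort, "cube", "spearman")$r, 1)
  expect_lt(ga_correlation(cohort, "cube", "pearson")$r, 1)

  cohort$flat <- 5
  expect_error(ga_correlation(cohort, "flat"), "zero variance")

  set.seed(50)
  big <- as_cohort_table(data.frame(
    subject_id = sprintf("S%05d", 1:10000),
    group = "adverse",
    ga_mri = rnorm(10000), indep = rnorm(10000)))
  expect_lt(abs(ga_correlation(big, "indep", "pearson")$r), 0.05)
})
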