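test_that("repeated-measures comparison matches the closed-form Friedman ranks", {
  # identical values at every time-point: statistic 0, p = 1
  flat <- expand.grid(animal = paste0("A", 1:8), time_point = c(0, 1, 2.5))
  flat$value <- 300
  r <- compare_repeated(flat)
  expect_equal(r$friedman$statistic, 0)
  expect_equal(r$friedman$p_value, 1)
  # strictly increasing across k = 4 time-points for every animal:
  # perfectly ordered ranks give the maximal statistic n * (k - 1) = 3n
  n <- 7
  inc <- expand.grid(animal = paste0("A", 1:n), time_point = c(0, 1, 2.5, 5))
  inc$value <- 300 + 10 * as.numeric(factor(inc$time_point)) +
    0.01 * as.numeric(factor(inc$animal))
  r2 <- compare_repeated(inc)
  expect_equal(r2$friedman$statistic, 3 * n)
  expect_equal(nrow(r2$pairwise), 3)
  expect_true(all(r2$pairwise$p_bonferroni >= r2$pairwise$p_raw))
  # permuting animal order changes nothing
  perm <- inc[sample(nrow(inc)), ]
  r3 <- compare_repeated(perm)
  expect_equal(r3$friedman$statistic, r2$friedman$statistic)
})

test_that("logistic OR on a saturated binary design equals the cross-product ratio", {
  # 2x2 cells: exposed 8 VF / 1 no-VF, unexposed 2 VF / 7 no-VF
  outcome <- c(rep(TRUE, 8), rep(FALSE, 1), rep(TRUE, 2), rep(FALSE, 7))
  exposed <- c(rep(1, 9), rep(0, 9))
  fit <- univariate_logistic(outcome, exposed)
  expect_equal(fit$estimate, 28, tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
  # affine rescaling of the covariate: p unchanged, log-OR scales
  fit_s <- univariate_logistic(outcome, exposed / 10)
  expect_equal(fit_s$p_value, fit$p_value, tolerance = 1e-6)
  expect_equal(log(fit_s$estimate) / 10, log(fit$estimate), tolerance = 1e-4)
})

test_that("logistic regression flags degenerate inputs", {
  expect_error(univariate_logistic(rep(TRUE, 10), rnorm(10)), "both outcome")
  sep <- univariate_logistic(c(rep(TRUE, 10), rep(FALSE, 10)),
                             c(rnorm(10, 10), rnorm(10, -10)))
  expect_equal(sep$flag, "separation")
})

test_that("Wald CIs of a null logistic covariate cover OR = 1 at ~95%", {
  set.seed(14)
  cover <- vapply(1:200, function(i) {
    y <- rbinom(500, 1, 0.5)
    x <- rnorm(500, 300, 40)
    f <- univariate_logistic(y, x)
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("linear regression recovers exact and limiting slopes", {
  x <- seq(300, 400, by = 5)
  f <- univariate_linear(x, x)
  expect_equal(f$estimate, 1)
  expect_lt(f$ci_high - f$ci_low, 1e-8)
  set.seed(2)
  f2 <- univariate_linear(0.5 * x + rnorm(length(x), 0, 1e-6), x)
  expect_equal(f2$estimate, 0.5, tolerance = 1e-6)
  expect_error(univariate_linear(x, rep(1, length(x))), "zero variance")
  expect_error(univariate_linear(x[1:2], x[1:2]), "n >= 3")
})

test_that("ROC analysis matches brute-force concordance and exhaustive Youden", {
  # hand example: 4 events {10,20,30,40} vs 4 non-events {5,15,25,35}
  y <- c(rep(TRUE, 4), rep(FALSE, 4))
  x <- c(10, 20, 30, 40, 5, 15, 25, 35)
  r <- roc_analysis(y, x)
  expect_equal(r$auc, 10 / 16)
  # perfectly separated groups
  r2 <- roc_analysis(c(TRUE, TRUE, FALSE, FALSE), c(10, 9, 2, 1))
  expect_equal(r2$auc, 1)
  expect_equal(r2$sens_at_cutoff, 1)
  expect_equal(r2$spec_at_cutoff, 1)
  # all ties
  r3 <- roc_analysis(c(TRUE, FALSE, TRUE, FALSE), rep(5, 4))
  expect_equal(r3$auc, 0.5)
  # property: equality with the all-pairs count on random cohorts
  set.seed(31)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    y <- as.logical(rbinom(n, 1, 0.5))
    if (length(unique(y)) < 2) next
    x <- round(rnorm(n, 450, 30), sample(0:1, 1))   # induce some ties
    r <- roc_analysis(y, x)
    expect_identical(r$auc, oracle_auc(y, x))
    o <- oracle_youden(y, x)
    expect_identical(r$optimal_cutoff, o$cutoff)
    expect_equal(r$sens_at_cutoff + r$spec_at_cutoff - 1, o$j)
  }
})

test_that("ROC AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- as.logical(rbinom(40, 1, 0.5))
  x <- rnorm(40, 450 + 20 * y, 30)
  r <- roc_analysis(y, x)
  ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE, direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("Cox regression handles degenerate and symmetric designs", {
  const <- cox_univariate(c(2, 4, 6, 10), c(TRUE, TRUE, FALSE, FALSE), rep(5, 4))
  expect_equal(const$flag, "constant covariate")
  # identical event-time patterns in the two covariate groups: HR = 1
  sym <- cox_univariate(c(2, 5, 10, 2, 5, 10),
                        c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                        c(0, 0, 0, 1, 1, 1))
  expect_equal(sym$estimate, 1, tolerance = 1e-8)
  expect_error(cox_univariate(c(1, 2), c(FALSE, FALSE), c(1, 2)), "no events")
})

test_that("Cox Wald CIs cover the true hazard ratio at ~95%", {
  set.seed(15)
  cover <- vapply(1:150, function(i) {
    x <- rnorm(300)
    t <- rexp(300, rate = 0.1 * exp(log(1.5) * x))
    cens <- pmin(t, 15)
    f <- cox_univariate(cens, t <= 15, x)
    f$ci_low <= 1.5 && 1.5 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("log-rank statistic matches the hand-computed worked example", {
  # group A: events at 1 and 2; group B: both censored at 10
  time <- c(1, 2, 10, 10); event <- c(TRUE, TRUE, FALSE, FALSE)
  group <- c("A", "A", "B", "B")
  km <- km_logrank(time, event, group)
  # t=1: O-E = 1 - 2/4, V = (3/3)*(2*2/16); t=2: O-E = 1 - 1/3, V = (2/2)*(1*2/9)
  oe <- (1 - 0.5) + (1 - 1 / 3)
  v <- 0.25 + 2 / 9
  expect_equal(km$logrank_statistic, oe^2 / v, tolerance = 1e-10)
  expect_equal(km$logrank_statistic, oracle_logrank(time, event, group),
               tolerance = 1e-10)
  expect_equal(km$p_value, pchisq(oe^2 / v, 1, lower.tail = FALSE))
  # identical groups: statistic 0
  km0 <- km_logrank(c(1, 3, 1, 3), c(TRUE, TRUE, TRUE, TRUE),
                    c("A", "A", "B", "B"))
  expect_lt(km0$logrank_statistic, 1e-12)
  # duplicated cohort: statistic grows and still matches the first-principles
  # O-E / hypergeometric-variance oracle (the variance factor (n-d)/(n-1)
  # keeps pooled duplication from exactly doubling the statistic)
  km2 <- km_logrank(rep(time, 2), rep(event, 2), rep(group, 2))
  expect_equal(km2$logrank_statistic,
               oracle_logrank(rep(time, 2), rep(event, 2), rep(group, 2)),
               tolerance = 1e-10)
  expect_gt(km2$logrank_statistic, km$logrank_statistic)
})

test_that("Kaplan-Meier with no censoring equals the empirical survival function", {
  set.seed(9)
  t1 <- sample(1:9, 12, replace = TRUE)
  t2 <- sample(2:10, 12, replace = TRUE)
  km <- km_logrank(c(t1, t2), rep(TRUE, 24), rep(c("A", "B"), each = 12))
  for (g in c("A", "B")) {
    tt <- if (g == "A") t1 else t2
    cu <- km$curves[km$curves$group == g, ]
    emp <- vapply(cu$time, function(u) mean(tt > u), numeric(1))
    expect_equal(cu$survival, emp)
    expect_true(all(diff(cu$survival) <= 1e-12))
  }
})

test_that("site chi-square reproduces the 2x2 Pearson statistic without correction", {
  site <- rep(c("LAD", "LCX"), each = 9)
  vf <- c(rep(TRUE, 5), rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 5))
  r <- site_chisquare(site, vf)
  expect_equal(signif(r$statistic, 3), 0.222)
  # balanced table: 0; swapping rows changes nothing
  r0 <- site_chisquare(rep(c("LAD", "LCX"), each = 10),
                       rep(c(TRUE, FALSE), 10))
  expect_equal(r0$statistic, 0)
  r_swap <- site_chisquare(rep(c("LCX", "LAD"), each = 9), vf)
  expect_equal(r_swap$statistic, r$statistic)
  expect_error(site_chisquare(rep("LAD", 4), c(TRUE, TRUE, FALSE, FALSE)), "2x2")
})

test_that("the VF association battery returns tidy per-covariate rows", {
  ds <- make_test_cohort(n_animals = 8, signals = FALSE, seed = 12,
                         noise_sd = 0.01)
  # animal-level summaries straight from ground truth (no waveforms needed)
  gt <- ds$ground_truth
  agg <- aggregate(cbind(true_aric, true_at) ~ animal + time_point, gt, max)
  summaries <- data.frame(animal = agg$animal, time_point = agg$time_point,
                          aric_max = agg$true_aric, at_max = agg$true_at)
  tab <- vf_association_table(summaries, ds$cohort,
                              covariates = c("aric_max", "at_max"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("estimate", "ci_low", "ci_high", "p_value", "n") %in% names(tab)))
  expect_true(all(tab$mode == "pooled"))
  tab2 <- vf_association_table(summaries, ds$cohort,
                               covariates = "aric_max", mode = "per_animal_max")
  expect_equal(tab2$n, 8)
})
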