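test_that("Pearson correlation recovers exact linear relations", {
  x <- 1:20
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  set.seed(30)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(pearson_corr(a, b)$r), 0.1)
  expect_warning(res <- pearson_corr(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(res$undefined)
  expect_error(pearson_corr(1:3, 1:4), "lengths differ")
})

test_that("summary-statistics ANOVA reproduces the printed group comparison", {
  res <- anova_from_summary(c(62.3, 54.1), c(6.6, 8.0), c(22, 22))
  expect_equal(round(res$p, 3), 0.001)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 42)
})

test_that("summary ANOVA is exact against raw-data ANOVA and the pooled t", {
  specs <- list(c(62.3, 6.6, 22, 54.1, 8.0, 22),
                c(10, 2, 5, 12, 3, 8),
                c(100, 15, 40, 95, 10, 30))
  for (s in specs) {
    x1 <- data_with_summary(s[3], s[1], s[2])
    x2 <- data_with_summary(s[6], s[4], s[5])
    raw <- data.frame(y = c(x1, x2),
                      g = rep(c("a", "b"), c(s[3], s[6])))
    a_raw <- anova(lm(y ~ g, data = raw))
    res <- anova_from_summary(c(s[1], s[4]), c(s[2], s[5]), c(s[3], s[6]))
    expect_equal(res$F, a_raw[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p, a_raw[["Pr(>F)"]][1], tolerance = 1e-10)
    tt <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("degenerate summary ANOVAs behave", {
  same <- anova_from_summary(c(50, 50), c(5, 7), c(10, 10))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("the regression reports the SCT slope per 100 um with its CI", {
  set.seed(31)
  n <- 60
  d <- data.frame(age = runif(n, 20, 70), axial_length = runif(n, 21, 26),
                  sct = runif(n, 150, 550))
  d$cvd <- 50 + 3.9 * d$sct / 100 + rnorm(n, 0, 3)
  fit <- fit_cvd_regression(d)
  co <- fit$coefficients["sct_per_100um", ]
  expect_lt(co$ci_lower, 3.9)
  expect_gt(co$ci_upper, 3.9)
  expect_lt(abs(co$estimate - 3.9), 1.5)
  expect_true(all(fit$coefficients$ci_lower <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$ci_upper >= fit$coefficients$estimate))
})

test_that("a constant response yields zero slopes", {
  d <- data.frame(age = runif(20, 20, 70), axial_length = runif(20, 21, 26),
                  sct = runif(20, 150, 550), cvd = 55)
  fit <- suppressWarnings(fit_cvd_regression(d))
  expect_equal(unname(fit$coefficients$estimate), c(0, 0, 0),
               tolerance = 1e-10)
  expect_error(fit_cvd_regression(d[1:5, ]), "at least 10")
})

test_that("ANCOVA removes an SCT confound and degrades gracefully", {
  set.seed(32)
  n <- 40
  sct <- c(rnorm(n / 2, 330, 90), rnorm(n / 2, 550, 110))
  grp <- rep(c("healthy", "csc"), each = n / 2)
  cvd <- 43 + 3.9 * sct / 100 + rnorm(n, 0, 7)  # no true group effect
  d <- data.frame(cvd = cvd, group = grp, sct = sct)
  res <- ancova_group_effect(d)
  anova_only <- anova_from_summary(tapply(cvd, grp, mean),
                                   tapply(cvd, grp, sd),
                                   as.vector(table(grp)))
  # the confounded one-way comparison is far more "significant"
  expect_gt(res$p, anova_only$p)
  expect_true(res$covariate_used)
  expect_named(res$adjusted_means, c("csc", "healthy"))

  # constant covariate: reduces to one-way ANOVA
  d2 <- data.frame(cvd = cvd, group = grp, sct = 400)
  expect_message(res2 <- ancova_group_effect(d2), "one-way")
  raw_p <- anova(lm(cvd ~ group, data = d2))[["Pr(>F)"]][1]
  expect_equal(res2$p, raw_p, tolerance = 1e-12)
  expect_false(res2$covariate_used)
})

test_that("the Lilliefors test flags non-normal samples and rejects constants", {
  set.seed(33)
  expect_gt(ks_normality(rnorm(500))$p, 0.05)
  expect_lt(ks_normality(rexp(500))$p, 0.05)
  expect_warning(res <- ks_normality(rep(2, 10)), "constant")
  expect_true(res$degenerate)
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("control matching is exact on sex and greedy-nearest on age and AL", {
  cases <- data.frame(eye_id = c("c1", "c2"), age = c(40, 60),
                      sex = c("M", "F"), axial_length = c(23.0, 24.0),
                      stringsAsFactors = FALSE)
  pool <- data.frame(
    eye_id = c("p1", "p2", "p3", "p4"),
    age = c(39, 70, 61, 41),
    sex = c("M", "M", "F", "F"),
    axial_length = c(23.1, 23.0, 24.1, 24.0),
    stringsAsFactors = FALSE)
  m <- match_controls(cases, pool)
  expect_equal(m$eye_id, c("p1", "p3"))
  expect_equal(m$sex, cases$sex)
  # exhausting a sex stratum fails loudly (three M cases, two M controls)
  m3 <- cases[c(1, 1, 1), ]
  expect_error(match_controls(m3, pool), "control available")
})
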