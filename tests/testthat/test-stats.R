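# Welch's t, batch-adjusted ANOVA, Tukey HSD, stars, embryo aggregation.

test_that("welch_t follows the closed-form statistic", {
  # identical groups: t = 0, p = 1
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # a +10 shift with unit variances: |t| = 10 / sqrt(2/3)
  r2 <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(abs(r2$statistic), 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(r2$p_value, 0.01)
  # antisymmetry under group swap
  r3 <- welch_t(c(11, 12, 13), c(1, 2, 3))
  expect_equal(r3$statistic, -r2$statistic)
  expect_equal(r3$p_value, r2$p_value)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(2, 2, 2), c(3, 3)), "zero variance")
})

test_that("welch_t matches reference implementations to 1e-10", {
  withr::local_seed(21)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    r <- welch_t(a, b)
    o <- oracle_welch(a, b)
    tt <- t.test(a, b)
    expect_lt(abs(r$statistic - o$t), 1e-10)
    expect_lt(abs(r$p_value - o$p), 1e-10)
    expect_lt(abs(r$statistic - unname(tt$statistic)), 1e-10)
    expect_lt(abs(r$p_value - tt$p.value), 1e-10)
    expect_lt(abs(r$df - unname(tt$parameter)), 1e-8)
  }
})

test_that("batch-adjusted ANOVA reduces to the pooled t-test in one batch", {
  withr::local_seed(22)
  df <- tibble::tibble(
    value = rnorm(16), group = rep(c("ctl", "trt"), each = 8),
    batch = "e1")
  a <- anova_with_batch(df)
  t2 <- t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(a$statistic, unname(t2$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, t2$p.value, tolerance = 1e-10)
})

test_that("ANOVA handles batch effects and rejects aliased designs", {
  withr::local_seed(23)
  # equal group means with strong batch effects: group F stays small
  df <- tidyr::expand_grid(group = c("a", "b", "c"), batch = c("e1", "e2"),
                           rep = 1:4)
  df$value <- rnorm(nrow(df)) + ifelse(df$batch == "e1", 0, 5)
  a <- anova_with_batch(df)
  expect_gt(a$p_value, 0.001)
  expect_true(!is.null(a$error_ms) && a$error_df > 0)
  # group identical to batch: aliased
  bad <- tibble::tibble(value = rnorm(12),
                        group = rep(c("a", "b"), each = 6),
                        batch = rep(c("e1", "e2"), each = 6))
  expect_error(anova_with_batch(bad), "aliased")
  expect_error(anova_with_batch(df[df$group == "a", ]), "2 groups")
})

test_that("ANOVA type-I error is calibrated under batch-effect nulls", {
  withr::local_seed(24)
  nsim <- 400
  rej <- 0
  for (s in seq_len(nsim)) {
    df <- tidyr::expand_grid(group = c("a", "b", "c"),
                             batch = c("e1", "e2", "e3"), rep = 1:3)
    df$value <- rnorm(nrow(df)) + as.integer(factor(df$batch)) * 2
    if (anova_with_batch(df)$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / nsim - 0.05), 0.025)
})

test_that("Tukey HSD with two groups equals the pooled t-test", {
  withr::local_seed(25)
  df <- tibble::tibble(value = rnorm(20, sd = 2),
                       group = rep(c("a", "b"), each = 10))
  fit <- lm(value ~ group, data = df)
  tk <- suppressWarnings(
    tukey_hsd(df, error_ms = sum(residuals(fit)^2) / fit$df.residual,
              error_df = fit$df.residual, gate = NULL))
  t2 <- t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(tk$p_adj, t2$p.value, tolerance = 1e-6)
  expect_equal(tk$q, abs(unname(t2$statistic)) * sqrt(2), tolerance = 1e-10)
})

test_that("Tukey HSD separates only the shifted group", {
  withr::local_seed(26)
  df <- tibble::tibble(
    value = c(rnorm(8), rnorm(8), rnorm(8) + 8),
    group = rep(c("a", "b", "c"), each = 8),
    batch = rep(rep(c("e1", "e2"), each = 4), 3))
  a <- anova_with_batch(df)
  expect_lt(a$p_value, 0.05)
  tk <- tukey_hsd(df, error_ms = a$error_ms, error_df = a$error_df,
                  anova_p = a$p_value)
  expect_identical(nrow(tk), 3L)
  sig <- tk$p_adj < 0.05
  involved <- (tk$group1 == "c") | (tk$group2 == "c")
  expect_identical(sig, involved)
  # identical group means: all adjusted p near 1
  df0 <- tibble::tibble(value = rep(c(1.02, 0.98, 1.01, 0.99), 3),
                        group = rep(c("a", "b", "c"), each = 4))
  tk0 <- suppressWarnings(tukey_hsd(df0, gate = NULL))
  expect_true(all(tk0$p_adj > 0.95))
  # and matches R's TukeyHSD on the same one-way fit
  fit <- aov(value ~ group, data = df)
  ref <- TukeyHSD(fit)$group[, "p adj"]
  tk1 <- suppressWarnings(
    tukey_hsd(df, error_ms = sum(residuals(fit)^2) / fit$df.residual,
              error_df = fit$df.residual, gate = NULL))
  expect_equal(sort(tk1$p_adj), sort(unname(ref)), tolerance = 1e-8)
})

test_that("family-wise error of Tukey under the null stays at or below 5%", {
  withr::local_seed(27)
  nsim <- 400
  fam <- 0
  for (s in seq_len(nsim)) {
    df <- tibble::tibble(value = rnorm(18), group = rep(c("a", "b", "c"), 6))
    tk <- suppressWarnings(tukey_hsd(df, gate = NULL))
    if (any(tk$p_adj < 0.05)) fam <- fam + 1
  }
  expect_lt(fam / nsim, 0.05 + 0.025)
})

test_that("significance stars follow the figure-legend convention", {
  expect_identical(significance_stars(c(0.004, 0.009, 0.03, 0.5)),
                   c("***", "**", "*", ""))
  expect_identical(significance_stars(0.005), "**")   # boundary is strict
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("embryo aggregation averages replicates before testing", {
  df <- tibble::tibble(
    embryo_id = rep(c("em1", "em2"), each = 4),
    group = rep("ctl", 8),
    xz_ratio = c(0.4, 0.6, 0.5, 0.5, 0.8, 0.8, 0.7, 0.9))
  ag <- aggregate_embryos(df, value = "xz_ratio")
  expect_identical(nrow(ag), 2L)
  expect_equal(sort(ag$xz_ratio), c(0.5, 0.8))
})

test_that("tidy and glance return one-row summaries", {
  r <- welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  td <- tidy(r)
  expect_identical(nrow(td), 1L)
  expect_identical(td$method, "welch_t")
  gl <- glance(r)
  expect_identical(gl$n_total, 8L)
})
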