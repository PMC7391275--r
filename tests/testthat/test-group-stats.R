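test_that("Spearman rho matches hand-ranked Pearson and handles edge cases", {
  expect_equal(spearman_test(1:5, c(2, 4, 6, 7, 9))$statistic, 1)
  expect_equal(spearman_test(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  r <- spearman_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$statistic, 0.8)

  # equals Pearson on mid-ranks, ties included
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_test(x, y)$statistic, cor(rank(x), rank(y)))
  }

  # t-approximation p agrees with cor.test's asymptotic route
  set.seed(6)
  x <- rnorm(15); y <- 0.5 * x + rnorm(15)
  ours <- spearman_test(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$statistic, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # exact permutation p for small n agrees with cor.test's exact p
  x <- c(3, 1, 4, 5, 2); y <- c(2, 1, 5, 4, 3)
  ours <- spearman_test(x, y, exact = TRUE)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("Mann-Whitney U, its p-value, and A match enumeration oracles", {
  r <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)  # no x exceeds any y

  expect_equal(mann_whitney_test(c(2, 3), c(1, 2))$effect, 0.875)
  expect_equal(vargha_delaney_A(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(vargha_delaney_A(c(10, 11), c(1, 2)), 1)
  expect_equal(vargha_delaney_A(c(5, 5), c(5, 5)), 0.5)

  # A-U identity and complementarity on random tied and untied inputs
  set.seed(7)
  for (i in 1:1000) {
    x <- sample(1:8, sample(2:6, 1), replace = TRUE)
    y <- sample(1:8, sample(2:6, 1), replace = TRUE)
    mw <- mann_whitney_test(x, y)
    expect_equal(mw$effect, mw$statistic / (length(x) * length(y)))
    expect_equal(vargha_delaney_A(x, y) + vargha_delaney_A(y, x), 1)
  }

  # U agrees with wilcox.test and the approximate p with its corrected
  # normal approximation
  set.seed(8)
  x <- rnorm(20); y <- rnorm(25, 0.7)
  ours <- mann_whitney_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # approximate p within tolerance of full permutation enumeration
  set.seed(9)
  for (i in 1:5) {
    x <- sample(1:9, 5, replace = TRUE)
    y <- sample(1:9, 5, replace = TRUE)
    approx_p <- mann_whitney_test(x, y)$p_value
    exact_p <- oracle_mw_exact_p(x, y)
    expect_lt(abs(approx_p - exact_p), 0.06)
  }

  expect_error(mann_whitney_test(numeric(0), 1:3), "empty group")
})

test_that("Holm correction reproduces the step-down scheme", {
  h <- holm_correct(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(h$adjusted, c(0.03, 0.04, 0.04))
  expect_true(all(h$reject))

  h2 <- holm_correct(c(0.04, 0.04), alpha = 0.05)
  expect_equal(h2$adjusted, c(0.08, 0.08))
  expect_false(any(h2$reject))

  expect_equal(holm_correct(0.031)$adjusted, 0.031)  # m = 1: identity

  # equals p.adjust and rejects a superset of Bonferroni
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    h <- holm_correct(p)
    expect_equal(h$adjusted, p.adjust(p, "holm"))
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(h$reject[bonf]))
  }
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("OLS reporting matches hand calculation and lm", {
  # 3-point toy: x = 0,1,2; y = 0,1,4 -> slope 2, intercept -1/3,
  # R^2 = SSR/SST = 8 / (26/3) = 12/13
  f <- fit_linear_model(c(0, 1, 4), data.frame(x = c(0, 1, 2)))
  expect_equal(unname(coef(f$fit)), c(-1 / 3, 2), tolerance = 1e-12)
  expect_equal(f$r2, 12 / 13, tolerance = 1e-12)

  y <- 2 * (1:10)
  fp <- suppressWarnings(fit_linear_model(y, data.frame(x = 1:10)))
  expect_equal(fp$r2, 1)
  expect_equal(fp$adj_r2, 1)

  set.seed(11)
  yn <- rnorm(1000)
  Xn <- data.frame(a = rnorm(1000), b = rnorm(1000))
  fn <- fit_linear_model(yn, Xn)
  expect_lt(abs(fn$adj_r2), 0.02)
  # adjusted never exceeds unadjusted
  expect_lte(fn$adj_r2, fn$r2)

  expect_error(fit_linear_model(rnorm(10),
                                data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear")
})

test_that("bootstrap CI for adjusted R^2 behaves at the extremes", {
  y <- 3 * (1:20) - 5
  X <- data.frame(x = 1:20)
  ci <- bootstrap_ci_adj_r2(y, X, reps = 100, seed = 1)
  expect_equal(c(ci$low, ci$high), c(1, 1))

  ci2 <- bootstrap_ci_adj_r2(y, X, reps = 100, seed = 1)
  expect_identical(ci$draws, ci2$draws)  # seeded determinism

  # null data: CI covers 0 in most seeded meta-repeats
  covered <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    yn <- rnorm(100)
    Xn <- data.frame(a = rnorm(100))
    ci <- bootstrap_ci_adj_r2(yn, Xn, reps = 200, seed = s)
    if (ci$low <= 0 && ci$high >= 0) covered <- covered + 1
  }
  expect_gte(covered / 20, 0.9)
})

test_that("out-of-bag prediction accuracy separates signal from null", {
  set.seed(12)
  x <- rnorm(60)
  y <- 2 * x + rnorm(60, 0, 1e-6)
  r <- bootstrap_prediction_r2(y, data.frame(x = x), resamples = 50, seed = 1)
  expect_gt(r$mean, 0.99)

  yn <- rnorm(60)
  rn <- bootstrap_prediction_r2(yn, data.frame(x = x), resamples = 100,
                                seed = 2)
  expect_lt(rn$mean, 0.05)  # optimism-corrected: near or below zero
  r2 <- bootstrap_prediction_r2(y, data.frame(x = x), resamples = 50,
                                seed = 1)
  expect_identical(r$draws, r2$draws)
})

test_that("sensitivity rerun pins the sample-SD convention and trims outliers", {
  v <- c(0, 0, 10)
  z3 <- (v[3] - mean(v)) / sd(v)
  expect_equal(z3, 1.1547, tolerance = 1e-4)

  # no outliers: trimmed result identical to full
  set.seed(13)
  idx <- rnorm(20)
  out <- 0.5 * idx + rnorm(20, 0, 0.5)
  r <- sensitivity_rerun(idx, out)
  expect_length(r$dropped, 0)
  expect_equal(r$trimmed$statistic, r$full$statistic)

  # a 10-SD outlier driving a spurious correlation is removed and the
  # trimmed estimate attenuates toward the outlier-free value
  set.seed(14)
  idx <- c(rnorm(24), 40)
  out <- c(rnorm(24), -60)
  r <- sensitivity_rerun(idx, out, ids = sprintf("s%02d", 1:25))
  expect_equal(r$dropped, "s25")
  base_rho <- spearman_test(idx[1:24], out[1:24])$statistic
  expect_lt(abs(r$trimmed$statistic - base_rho),
            abs(r$full$statistic - base_rho))
})

test_that("the full battery reports a stable set of tests with Holm per family", {
  fx <- tiny_cohort(n_normative = 25, n_atypical = 12, seed = 21,
                    grid_shape = c(7, 7, 7))
  nv <- dim(fx$dataset$values)[2]
  set.seed(15)
  z <- array(rnorm(nrow(fx$table) * nv * 2), c(nrow(fx$table), nv, 2),
             dimnames = list(fx$table$subject_id, NULL, c("FA", "MD")))
  rec <- atypicality_index(dev_from_z(z, threshold = 3.1))
  tab <- atypicality_table(rec, fx$table)
  b1 <- run_full_battery(tab, seed = 1, bootstrap_reps = 50,
                         prediction_resamples = 20)
  b2 <- run_full_battery(tab, seed = 1, bootstrap_reps = 50,
                         prediction_resamples = 20)
  expect_identical(b1$report, b2$report)
  # 4 group tests + 2 x 4 GA + 2 x 12 outcome correlations
  expect_equal(nrow(b1$report), 4 + 8 + 24)
  # Holm was applied within each family
  for (fam in unique(paste(b1$report$family, b1$report$group))) {
    sel <- paste(b1$report$family, b1$report$group) == fam &
      !is.na(b1$report$p)  # degenerate (constant-index) tests sit out
    expect_equal(b1$report$p_adj[sel],
                 holm_correct(b1$report$p[sel])$adjusted)
  }

  # missing outcome columns are skipped with a warning, never silently
  tab2 <- tab[, setdiff(names(tab), "outcome_motor")]
  expect_warning(b3 <- run_full_battery(tab2, seed = 1, bootstrap_reps = 50,
                                        prediction_resamples = 20),
                 "outcome_motor")
  expect_equal(nrow(b3$report), 4 + 8 + 16)
})
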