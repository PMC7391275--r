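test_that("standardization inverts exactly and pins the SD convention", {
  set.seed(1)
  Y <- cbind(runif(10, 0.1, 0.5), runif(10, 0.8, 1.3))
  pma <- runif(10, 37, 45)
  sex <- rbinom(10, 1, 0.5)
  s <- standardize_design(Y, pma, sex)
  back <- cbind(s$y[1:10] * s$y_sd[1] + s$y_mean[1],
                s$y[11:20] * s$y_sd[2] + s$y_mean[2])
  expect_equal(back, Y, tolerance = 1e-14)

  # sample-SD (n - 1) convention: outputs {1,2,3} standardize to {-1, 0, 1}
  s2 <- standardize_design(cbind(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 3)),
                           c(38, 40, 42, 39, 41), c(0, 1, 0, 1, 0))
  expect_equal(sd(c(1, 2, 3)), 1)  # the convention the first 3 values probe
  sfa <- (c(1, 2, 3, 2, 1) - mean(c(1, 2, 3, 2, 1))) / sd(c(1, 2, 3, 2, 1))
  expect_equal(s2$y[1:5], sfa)

  expect_error(standardize_design(Y, rep(40, 10), sex), "predictor variance")
  expect_error(standardize_design(Y[1:3, ], pma[1:3], sex[1:3]), "at least 5")
  Yd <- Y
  Yd[, 2] <- 1
  expect_error(standardize_design(Yd, pma, sex),
               class = "voxnorm_degenerate")
})

test_that("log marginal likelihood matches closed form and a dense oracle", {
  # two independent unit-variance observations at one input, targets 0:
  # lml = 2 * (-1/2 log 2pi)
  th <- c(log(1), log(sqrt(0.5)), 0, log(sqrt(0.5)), log(0.5), log(0.5))
  x1 <- matrix(c(0, 0), 1, 2)
  expect_equal(gp_log_marginal(th, x1, c(0, 0), jitter = 0),
               -log(2 * pi), tolerance = 1e-9)

  # random n = 4 instances against the dense brute-force oracle
  set.seed(7)
  for (rep in 1:5) {
    x <- cbind(rnorm(4), rbinom(4, 1, 0.5))
    y <- rnorm(8)
    th <- c(log(runif(1, 0.3, 3)), log(runif(1, 0.3, 1)), rnorm(1, 0, 0.5),
            log(runif(1, 0.3, 1)), log(runif(1, 0.1, 1)),
            log(runif(1, 0.1, 1)))
    expect_equal(gp_log_marginal(th, x, y), oracle_lml(th, x, y),
                 tolerance = 1e-8)
  }

  # with y = 0, inflating the noise grows log|K| and so lowers the lml
  y0 <- rep(0, 8)
  x <- cbind(rnorm(4), rbinom(4, 1, 0.5))
  th_lo <- c(0, log(0.7), 0.2, log(0.7), log(0.3), log(0.3))
  th_hi <- th_lo
  th_hi[5:6] <- log(0.6)
  expect_gt(gp_log_marginal(th_lo, x, y0), gp_log_marginal(th_hi, x, y0))
})

test_that("posterior prediction matches the dense oracle to 1e-8", {
  fx <- make_linear_dataset(n = 6, nv = 1, noise = c(0.02, 0.05), seed = 3)
  m <- fit_voxel(fx$dataset, 1, fx$table, config = gp_config(restarts = 2))
  xq <- cbind(c(-0.9, 0.4, 2.0), c(0, 1, 1))
  pma_q <- xq[, 1] * m$pma_sd + m$pma_mean
  for (noise in c(TRUE, FALSE)) {
    p <- suppressWarnings(predict(m, pma_q, xq[, 2], include_noise = noise))
    o <- oracle_posterior(m$theta, m$x, xq, m$y, include_noise = noise)
    # compare on the standardized scale where the 1e-8 contract is defined
    expect_equal((p$mean[, 1] - m$y_mean[1]) / m$y_sd[1], o$mean[, 1],
                 tolerance = 1e-8)
    expect_equal((p$mean[, 2] - m$y_mean[2]) / m$y_sd[2], o$mean[, 2],
                 tolerance = 1e-8)
    expect_equal(p$sd[, 1] / m$y_sd[1], o$sd[, 1], tolerance = 1e-8)
    expect_equal(p$sd[, 2] / m$y_sd[2], o$sd[, 2], tolerance = 1e-8)
  }
})

test_that("the fitted-model likelihood accessor recomputes the optimized value", {
  fx <- make_linear_dataset(n = 15, nv = 1, seed = 5)
  m <- fit_voxel(fx$dataset, 1, fx$table, config = gp_config(restarts = 2))
  expect_equal(log_marginal_likelihood(m), m$lml, tolerance = 1e-6)
  expect_true(is.finite(m$lml))
})

test_that("noiseless data is interpolated and far queries revert to the prior", {
  fx <- make_linear_dataset(n = 20, nv = 1, noise = c(1e-9, 1e-9), seed = 4)
  m <- fit_voxel(fx$dataset, 1, fx$table)
  p <- predict(m, fx$pma, fx$sex, include_noise = FALSE)
  z_fa <- (p$mean[, 1] - fx$dataset$values[, 1, "FA"]) / m$y_sd[1]
  expect_lt(max(abs(z_fa)), 1e-3)

  # far query: mean reverts to the training mean, variance to the prior
  far <- suppressWarnings(predict(m, 40 + 1e4 * m$pma_sd, 0,
                                  include_noise = TRUE))
  expect_true(far$extrapolated)
  expect_equal(far$mean[1, 1], m$y_mean[1], tolerance = 1e-6)
  L <- matrix(c(exp(m$theta[2]), m$theta[3], 0, exp(m$theta[4])), 2, 2)
  B <- L %*% t(L)
  prior_sd_fa <- sqrt(B[1, 1] + exp(m$theta[5])) * m$y_sd[1]
  expect_equal(far$sd[1, 1], prior_sd_fa, tolerance = 1e-6)

  # monotone uncertainty: noise-free variance at a training input does not
  # exceed the far-field variance
  near <- predict(m, fx$pma[1], fx$sex[1], include_noise = FALSE)
  far_nf <- suppressWarnings(predict(m, 40 + 1e4 * m$pma_sd, 0,
                                     include_noise = FALSE))
  expect_lte(near$sd[1, 1], far_nf$sd[1, 1] + 1e-12)
})

test_that("pure-noise voxels fit with low signal-to-noise ratio", {
  low_snr <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 40
    values <- array(c(rnorm(n, 0.3, 0.03), rnorm(n, 1.1, 0.08)),
                    c(n, 1, 2),
                    dimnames = list(sprintf("sub-%04d", 1:n), NULL,
                                    c("FA", "MD")))
    mask <- array(FALSE, c(4, 4, 4)); mask[1] <- TRUE
    ds <- voxel_dataset(values, mask)
    tab <- data.frame(subject_id = sprintf("sub-%04d", 1:n),
                      pma_scan = runif(n, 37, 45), sex = rbinom(n, 1, 0.5))
    m <- fit_voxel(ds, 1, tab, config = gp_config(seed = r))
    L <- matrix(c(exp(m$theta[2]), m$theta[3], 0, exp(m$theta[4])), 2, 2)
    B <- L %*% t(L)
    snr <- sum(diag(B)) / sum(exp(m$theta[5:6]))
    if (snr < 0.5) low_snr <- low_snr + 1
  }
  expect_gte(low_snr / reps, 0.9)
})

test_that("data simulated from the model's own kernel recovers the lengthscale", {
  true_th <- c(log(1.0), log(sqrt(0.6)), 0.3, log(sqrt(0.4)), log(0.4),
               log(0.4))
  ok <- 0
  reps <- 8
  for (r in seq_len(reps)) {
    set.seed(200 + r)
    n <- 200
    x <- cbind(runif(n, -1.7, 1.7), rbinom(n, 1, 0.5))
    kk <- oracle_build_K(true_th, x, jitter = 1e-8)
    y <- drop(t(chol(kk$K)) %*% rnorm(2 * n))
    # wrap into a dataset on the original scale (identity standardization is
    # not assumed; fit_voxel re-standardizes internally)
    pma <- x[, 1] * 2.3 + 41
    values <- array(c(y[1:n], y[(n + 1):(2 * n)]), c(n, 1, 2),
                    dimnames = list(sprintf("sub-%04d", 1:n), NULL,
                                    c("FA", "MD")))
    mask <- array(FALSE, c(4, 4, 4)); mask[1] <- TRUE
    tab <- data.frame(subject_id = sprintf("sub-%04d", 1:n),
                      pma_scan = pma, sex = x[, 2])
    m <- fit_voxel(voxel_dataset(values, mask), 1, tab,
                   config = gp_config(restarts = 2, seed = r))
    # the refit standardizes PMA by its own SD; compare lengthscales on the
    # standardized scale used for generation
    ell_hat <- exp(m$theta[1]) * m$pma_sd / 2.3
    if (ell_hat > 0.5 && ell_hat < 2.0) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.8)
})

test_that("metric storage order does not change predictions", {
  fx <- make_linear_dataset(n = 40, nv = 1, seed = 6)
  swapped <- fx$dataset$values[, , c(2, 1), drop = FALSE]
  dimnames(swapped)[[3]] <- c("MD", "FA")
  mask <- array(FALSE, c(4, 4, 4)); mask[1] <- TRUE
  ds2 <- voxel_dataset(swapped, mask)
  m1 <- fit_voxel(fx$dataset, 1, fx$table, config = gp_config(seed = 1))
  m2 <- fit_voxel(ds2, 1, fx$table, config = gp_config(seed = 1))
  p1 <- predict(m1, c(38, 41, 44), c(0, 1, 0))
  p2 <- predict(m2, c(38, 41, 44), c(0, 1, 0))
  expect_equal(p1$mean[, "FA"], p2$mean[, "FA"], tolerance = 1e-4)
  expect_equal(p1$mean[, "MD"], p2$mean[, "MD"], tolerance = 1e-4)
  expect_equal(p1$sd[, "FA"], p2$sd[, "FA"], tolerance = 1e-3)
  expect_equal(p1$sd[, "MD"], p2$sd[, "MD"], tolerance = 1e-3)
})

test_that("stratified folds partition subjects and span the PMA range", {
  set.seed(3)
  pma <- runif(50, 37, 45)
  folds <- assign_folds(pma, k = 5, seed = 2)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 50)  # every subject in exactly one fold
  full <- diff(range(pma))
  for (f in 1:5) {
    expect_gte(diff(range(pma[folds == f])) / full, 0.8)
  }
  expect_error(assign_folds(runif(8), k = 5), "fewer than 3")
})

test_that("cross-validation on near-noiseless data achieves tiny MAE", {
  fx <- make_linear_dataset(n = 30, nv = 2, noise = c(1e-4, 1e-4), seed = 8)
  cv <- crossvalidate(fx$dataset, fx$table, rows = fx$table$subject_id,
                      k = 5, seed = 1, config = gp_config(restarts = 2))
  expect_lt(cv$mean_mae["FA"], 1e-3)
  expect_lt(cv$mean_mae["MD"], 1e-3)
  # partition property: held-out predictions exist for every subject
  expect_false(anyNA(cv$pred_mean))
  expect_equal(sort(names(cv$folds)), sort(fx$table$subject_id))
})

test_that("fit_all is deterministic, order-independent, and store round-trips", {
  fx <- tiny_cohort(n_normative = 24, n_atypical = 0, grid_shape = c(5, 5, 5),
                    seed = 3)
  nv <- dim(fx$dataset$values)[2]
  keep <- seq_len(10)
  mask <- array(FALSE, fx$dataset$grid_shape)
  mask[fx$dataset$mask_index[keep]] <- TRUE
  ds <- voxel_dataset(fx$dataset$values[, keep, , drop = FALSE], mask)
  cfg <- gp_config(restarts = 2, seed = 7)

  m1 <- fit_all(ds, fx$table, config = cfg)
  m2 <- fit_all(ds, fx$table, config = cfg)
  expect_identical(m1$theta, m2$theta)

  m3 <- fit_all(ds, fx$table, config = cfg, voxel_order = rev(seq_len(10)))
  expect_identical(m1$theta, m3$theta)

  dir <- withr::local_tempdir()
  write_model_store(m1, dir)
  m4 <- read_model_store(dir, ds, fx$table)
  p1 <- predict_normative(m1, c(38, 42), c(0, 1))
  p4 <- predict_normative(m4, c(38, 42), c(0, 1))
  expect_equal(p1$mean, p4$mean, tolerance = 1e-12)
  expect_equal(p1$sd, p4$sd, tolerance = 1e-12)
})
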