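#' Optimizer configuration for per-voxel GP fits
#'
#' @param restarts Number of optimizer restarts per voxel (the first start is
#'   a data-driven initialisation, the rest are seeded jitters of it).
#' @param maxit Maximum L-BFGS-B iterations per restart.
#' @param factr L-BFGS-B relative convergence tolerance.
#' @param jitter Diagonal jitter (standardized scale) added to the joint
#'   covariance before factorization; escalated tenfold up to three times on
#'   failure.
#' @param seed Global seed from which per-voxel restart seeds are derived.
#' @param lower,upper Box bounds on the 6 log-scale kernel parameters
#'   (log lengthscale, log L11, L21, log L22, log noise FA, log noise MD).
#' @return A list of class `gp_config`.
#' @export
gp_config <- function(restarts = 3, maxit = 80, factr = 1e9, jitter = 1e-8,
                      seed = 1,
                      lower = c(log(0.05), -7, -5, -7, log(1e-6), log(1e-6)),
                      upper = c(log(50), 2, 5, 2, 2, 2)) {
  structure(list(restarts = as.integer(restarts), maxit = as.integer(maxit),
                 factr = factr, jitter = jitter, seed = as.integer(seed),
                 lower = lower, upper = upper),
            class = "gp_config")
}

#' Standardize a voxel's outputs and the cohort design
#'
#' Centres and scales each output by its training mean and sample SD
#' (n - 1 denominator), and PMA by its training mean/SD; sex is passed
#' through as a 0/1 coordinate. The constants are stored for exact
#' inversion. Standardization is what lets FA (~0.2, unitless) and MD
#' (~1 micrometer^2/ms) share one kernel.
#'
#' @param Y n x 2 matrix of outputs (FA, MD) at one voxel.
#' @param pma,sex Length-n covariates (weeks; 0 = female, 1 = male).
#' @return A list: `y` (stacked 2n standardized target, FA block then MD
#'   block), `x` (n x 2 standardized design), `y_mean`, `y_sd`, `pma_mean`,
#'   `pma_sd`, `pma_range`.
#' @export
standardize_design <- function(Y, pma, sex) {
  stopifnot(nrow(Y) == length(pma), length(pma) == length(sex))
  if (nrow(Y) < 5) stop("at least 5 training subjects are required")
  y_sd <- apply(Y, 2, sd)
  if (any(y_sd == 0)) {
    stop(structure(list(message = "zero-variance output at this voxel",
                        call = sys.call(-1)),
                   class = c("voxnorm_degenerate", "error", "condition")))
  }
  pma_sd <- sd(pma)
  if (pma_sd == 0) stop("zero predictor variance: PMA is constant")
  y_mean <- colMeans(Y)
  list(y = c((Y[, 1] - y_mean[1]) / y_sd[1], (Y[, 2] - y_mean[2]) / y_sd[2]),
       x = cbind((pma - mean(pma)) / pma_sd, sex),
       y_mean = y_mean, y_sd = y_sd,
       pma_mean = mean(pma), pma_sd = pma_sd, pma_range = range(pma))
}

#' Log marginal likelihood of the two-output GP
#'
#' Evaluates -1/2 y' K^-1 y - 1/2 log|K| - (N/2) log(2 pi), where K is the
#' joint (intrinsic-coregionalization) covariance over all (subject, output)
#' pairs, via a cached Cholesky factorization.
#'
#' @param theta Length-6 kernel parameter vector on the optimizer scale:
#'   log lengthscale, log L11, L21, log L22, log noise variances.
#' @param x n x 2 standardized design (pma_std, sex).
#' @param y Stacked 2n standardized target.
#' @param jitter Diagonal jitter.
#' @return The log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(theta, x, y, jitter = 1e-8) {
  D2 <- as.matrix(dist(x))^2
  r <- gp_nll_grad(theta, D2, y, jitter)
  if (!r$ok) stop("covariance not positive definite at maximum jitter")
  -r$nll
}

# Data-driven starting point: noise variances from linear-fit residuals of
# the standardized outputs, remaining variance assigned to the signal, and
# the cross-output coregionalization initialised from the output correlation.
initial_theta <- function(x, y1, y2) {
  v1 <- min(max(var(resid(lm(y1 ~ x))), 0.05), 0.95)
  v2 <- min(max(var(resid(lm(y2 ~ x))), 0.05), 0.95)
  s1 <- max(1 - v1, 0.05)
  s2 <- max(1 - v2, 0.05)
  rho <- cor(y1, y2)
  if (!is.finite(rho)) rho <- 0
  l11 <- sqrt(s1)
  l21 <- rho * sqrt(s2)
  l22 <- sqrt(max(s2 - l21^2, 0.01))
  c(log(1.5), log(l11), l21, log(l22), log(v1), log(v2))
}

# Core per-voxel optimization. D2 may be precomputed (shared design).
fit_gp_core <- function(std, config, voxel_index, D2 = NULL) {
  if (is.null(D2)) D2 <- as.matrix(dist(std$x))^2
  n <- nrow(std$x)
  y <- std$y
  obj <- function(th) gp_nll_grad(th, D2, y, config$jitter)$nll
  grad <- function(th) gp_nll_grad(th, D2, y, config$jitter)$grad
  init <- initial_theta(std$x, y[1:n], y[(n + 1):(2 * n)])
  init <- pmin(pmax(init, config$lower), config$upper)
  best <- NULL
  restarts_used <- 0L
  for (r in seq_len(config$restarts)) {
    th0 <- if (r == 1) init else {
      with_seed(derive_seed(config$seed, voxel_index * 17L + r),
                pmin(pmax(init + rnorm(6, 0, 0.4), config$lower),
                     config$upper))
    }
    o <- tryCatch(optim(th0, fn = obj, gr = grad, method = "L-BFGS-B",
                        lower = config$lower, upper = config$upper,
                        control = list(maxit = config$maxit,
                                       factr = config$factr)),
                  error = function(e) NULL)
    restarts_used <- restarts_used + 1L
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) {
      best <- o
    }
  }
  if (is.null(best)) {
    warning("GP optimizer failed on all restarts at voxel ", voxel_index)
    return(list(theta = rep(NA_real_, 6), lml = NA_real_, flag = "failed",
                converged = FALSE, restarts = restarts_used))
  }
  list(theta = best$par, lml = -best$value, flag = "ok",
       converged = best$convergence == 0, restarts = restarts_used)
}

#' Fit the two-output GP at a single voxel
#'
#' Maximises the log marginal likelihood over the kernel parameters by
#' quasi-Newton optimization on log-transformed positive parameters, taking
#' the best of several seeded restarts. Voxels whose outputs have zero
#' variance are returned as flagged degenerate models rather than fitted.
#'
#' @param dataset A `voxel_dataset`.
#' @param voxel Voxel index into the in-mask voxel list.
#' @param cohort Covariate table containing `subject_id`, `pma_scan`, `sex`.
#' @param rows Optional subject ids to train on (default: all in dataset).
#' @param config A [gp_config()].
#' @return An object of class `voxel_gp`.
#' @export
fit_voxel <- function(dataset, voxel, cohort, rows = NULL,
                      config = gp_config()) {
  cohort <- align_cohort(dataset, cohort, rows)
  idx <- match(cohort$subject_id, dataset$subject_ids)
  Y <- dataset$values[idx, voxel, , drop = TRUE]
  std <- tryCatch(standardize_design(Y, cohort$pma_scan, cohort$sex),
                  voxnorm_degenerate = function(e) NULL)
  if (is.null(std)) {
    fit <- list(theta = rep(NA_real_, 6), lml = NA_real_,
                flag = "degenerate", converged = FALSE, restarts = 0L)
    std <- list(y_mean = colMeans(Y), y_sd = apply(Y, 2, sd),
                pma_mean = mean(cohort$pma_scan), pma_sd = sd(cohort$pma_scan),
                pma_range = range(cohort$pma_scan),
                x = cbind(scale(cohort$pma_scan)[, 1], cohort$sex),
                y = rep(0, 2 * nrow(Y)))
  } else {
    fit <- fit_gp_core(std, config, voxel)
  }
  structure(c(fit, std,
              list(metrics = dataset$metrics, jitter = config$jitter,
                   subject_ids = cohort$subject_id, voxel = voxel)),
            class = "voxel_gp")
}

#' @export
print.voxel_gp <- function(x, ...) {
  cat("voxel_gp (", x$flag, "): lml =", format(x$lml), "n =", nrow(x$x),
      "\n")
  invisible(x)
}

#' Log marginal likelihood of a fitted voxel model
#'
#' @param model A `voxel_gp`.
#' @return Scalar log marginal likelihood at the fitted parameters.
#' @export
log_marginal_likelihood <- function(model) {
  stopifnot(inherits(model, "voxel_gp"))
  if (model$flag != "ok") return(NA_real_)
  gp_log_marginal(model$theta, model$x, model$y, model$jitter)
}

#' Predictive distribution at query subjects
#'
#' Standard GP posterior mean and variance at the query points, with the
#' per-output noise variance folded into the predictive SD when
#' `include_noise = TRUE` (the default, and the convention under which
#' downstream Z-scores are calibrated against total predictive
#' uncertainty). Mean and SD are returned in the metrics' original units.
#' Queries with PMA outside the training range are flagged as
#' extrapolations.
#'
#' @param object A fitted `voxel_gp`.
#' @param pma,sex Query covariates.
#' @param include_noise Fold noise variance into the predictive SD?
#' @param ... Unused.
#' @return A list of class `gp_prediction`: `mean` and `sd` (q x 2 matrices
#'   in original units), `extrapolated` (logical), `includes_noise`.
#' @export
predict.voxel_gp <- function(object, pma, sex, include_noise = TRUE, ...) {
  q <- length(pma)
  extrap <- pma < object$pma_range[1] | pma > object$pma_range[2]
  if (any(extrap)) {
    warning("query PMA outside the training range: prediction is an ",
            "extrapolation for ", sum(extrap), " subject(s)")
  }
  if (object$flag == "degenerate") {
    return(structure(list(mean = matrix(NA_real_, q, 2),
                          sd = matrix(NA_real_, q, 2), extrapolated = extrap,
                          includes_noise = include_noise),
                     class = "gp_prediction"))
  }
  xq <- cbind((pma - object$pma_mean) / object$pma_sd, sex)
  D2 <- as.matrix(dist(object$x))^2
  D2c <- cross_dist2(object$x, xq)
  r <- gp_predict_cpp(object$theta, D2, D2c, object$y, include_noise,
                      object$jitter)
  mean_orig <- sweep(sweep(r$mean, 2, object$y_sd, "*"), 2, object$y_mean, "+")
  sd_orig <- sweep(r$sd, 2, object$y_sd, "*")
  colnames(mean_orig) <- colnames(sd_orig) <- object$metrics
  structure(list(mean = mean_orig, sd = sd_orig, extrapolated = extrap,
                 includes_noise = include_noise),
            class = "gp_prediction")
}

cross_dist2 <- function(x, xq) {
  # n x q squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(xq))) +
    outer(rep(1, nrow(x)), rowSums(xq^2)) - 2 * x %*% t(xq)
}

align_cohort <- function(dataset, cohort, rows = NULL) {
  ids <- rows %||% intersect(cohort$subject_id, dataset$subject_ids)
  miss <- setdiff(ids, cohort$subject_id)
  if (length(miss)) stop("subject(s) absent from covariate table: ",
                         paste(head(miss, 5), collapse = ", "))
  miss <- setdiff(ids, dataset$subject_ids)
  if (length(miss)) stop("subject(s) absent from image data: ",
                         paste(head(miss, 5), collapse = ", "))
  cohort[match(ids, cohort$subject_id), , drop = FALSE]
}

#' Fit the normative GP at every in-mask voxel
#'
#' One independent model per voxel; results are identical regardless of the
#' order in which voxels are processed, because each voxel's restart seeds
#' derive from its index in the mask, not its processing order.
#'
#' @param dataset A `voxel_dataset`.
#' @param cohort Covariate table.
#' @param rows Subject ids to train on (default: subjects with
#'   `group == "normative"` if a group column is present, else all).
#' @param config A [gp_config()].
#' @param voxel_order Optional permutation of voxel indices (testing hook;
#'   the result is invariant to it).
#' @param verbose Log progress every 1000 voxels?
#' @return An object of class `normative_model` holding per-voxel kernel
#'   parameters, standardization constants, flags and optimizer diagnostics.
#' @export
fit_all <- function(dataset, cohort, rows = NULL, config = gp_config(),
                    voxel_order = NULL, verbose = FALSE) {
  if (is.null(rows) && "group" %in% names(cohort)) {
    rows <- cohort$subject_id[cohort$group == "normative"]
    rows <- intersect(rows, dataset$subject_ids)
  }
  cohort <- align_cohort(dataset, cohort, rows)
  idx <- match(cohort$subject_id, dataset$subject_ids)
  n <- length(idx)
  nv <- dim(dataset$values)[2]
  pma <- cohort$pma_scan
  pma_mean <- mean(pma)
  pma_sd <- sd(pma)
  if (pma_sd == 0) stop("zero predictor variance: PMA is constant")
  x <- cbind((pma - pma_mean) / pma_sd, cohort$sex)
  D2 <- as.matrix(dist(x))^2

  theta <- matrix(NA_real_, nv, 6)
  y_mean <- y_sd <- matrix(NA_real_, nv, 2)
  lml <- rep(NA_real_, nv)
  flag <- character(nv)
  converged <- logical(nv)
  Ystd <- matrix(0, nv, 2 * n)

  order_v <- voxel_order %||% seq_len(nv)
  done <- 0L
  for (v in order_v) {
    Y <- dataset$values[idx, v, , drop = TRUE]
    y_mean[v, ] <- colMeans(Y)
    y_sd[v, ] <- apply(Y, 2, sd)
    if (any(y_sd[v, ] == 0)) {
      flag[v] <- "degenerate"
      next
    }
    yv <- c((Y[, 1] - y_mean[v, 1]) / y_sd[v, 1],
            (Y[, 2] - y_mean[v, 2]) / y_sd[v, 2])
    Ystd[v, ] <- yv
    std <- list(x = x, y = yv)
    fit <- fit_gp_core(std, config, v, D2 = D2)
    theta[v, ] <- fit$theta
    lml[v] <- fit$lml
    flag[v] <- fit$flag
    converged[v] <- fit$converged
    done <- done + 1L
    if (verbose && done %% 1000 == 0) {
      message("fitted ", done, " / ", nv, " voxels")
    }
  }
  n_bad <- sum(flag != "ok")
  if (n_bad > 0) message(n_bad, " of ", nv,
                         " voxels flagged (degenerate or non-converged)")
  structure(list(theta = theta, y_mean = y_mean, y_sd = y_sd, lml = lml,
                 flag = flag, converged = converged, Ystd = Ystd, x = x,
                 D2 = D2, pma_mean = pma_mean, pma_sd = pma_sd,
                 pma_range = range(pma), subject_ids = cohort$subject_id,
                 metrics = dataset$metrics, config = config,
                 grid_shape = dataset$grid_shape,
                 mask_index = dataset$mask_index, affine = dataset$affine),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("normative_model:", nrow(x$theta), "voxels,",
      length(x$subject_ids), "training subjects;",
      sum(x$flag != "ok"), "flagged\n")
  invisible(x)
}

#' Predictive mean and SD for a set of subjects at every voxel
#'
#' @param model A `normative_model` from [fit_all()].
#' @param pma,sex Query covariates (one entry per subject to score).
#' @param include_noise Fold per-output noise variance into the SD?
#' @return List with `mean` and `sd`, each subjects x voxels x metrics;
#'   flagged voxels are NA.
#' @export
predict_normative <- function(model, pma, sex, include_noise = TRUE) {
  q <- length(pma)
  nv <- nrow(model$theta)
  xq <- cbind((pma - model$pma_mean) / model$pma_sd, sex)
  D2c <- cross_dist2(model$x, xq)
  mean_out <- array(NA_real_, c(q, nv, 2),
                    dimnames = list(NULL, NULL, model$metrics))
  sd_out <- mean_out
  for (v in seq_len(nv)) {
    if (model$flag[v] != "ok") next
    r <- gp_predict_cpp(model$theta[v, ], model$D2, D2c, model$Ystd[v, ],
                        include_noise, model$config$jitter)
    mean_out[, v, 1] <- model$y_mean[v, 1] + model$y_sd[v, 1] * r$mean[, 1]
    mean_out[, v, 2] <- model$y_mean[v, 2] + model$y_sd[v, 2] * r$mean[, 2]
    sd_out[, v, 1] <- model$y_sd[v, 1] * r$sd[, 1]
    sd_out[, v, 2] <- model$y_sd[v, 2] * r$sd[, 2]
  }
  list(mean = mean_out, sd = sd_out, includes_noise = include_noise)
}

#' Write / read a fitted model store
#'
#' The store is a directory holding a JSON header (schema version, training
#' subject ids, PMA standardization constants, optimizer config) and a TSV
#' of per-voxel kernel parameters, output standardization constants and
#' flags. Training targets are not duplicated in the store; they are
#' reattached from the dataset on read.
#'
#' @param model A `normative_model`.
#' @param path Directory to write to (created if needed).
#' @return `write_model_store` invisibly returns `path`;
#'   `read_model_store` returns a `normative_model`.
#' @export
write_model_store <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(schema = "voxnorm-model-1",
                 subject_ids = model$subject_ids,
                 pma_mean = model$pma_mean, pma_sd = model$pma_sd,
                 pma_range = model$pma_range, metrics = model$metrics,
                 grid_shape = model$grid_shape,
                 config = unclass(model$config))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- data.frame(model$theta, model$y_mean, model$y_sd, lml = model$lml,
                    flag = model$flag, converged = model$converged)
  names(tab)[1:10] <- c("log_ell", "log_l11", "l21", "log_l22",
                        "log_noise_fa", "log_noise_md", "mean_fa", "mean_md",
                        "sd_fa", "sd_md")
  write.table(format(tab, digits = 17), file.path(path, "voxels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param dataset,cohort The dataset and covariate table the model was
#'   trained on (for `read_model_store`).
#' @rdname write_model_store
#' @export
read_model_store <- function(path, dataset, cohort) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  if (!identical(header$schema, "voxnorm-model-1")) {
    stop("unrecognised model store schema: ", header$schema)
  }
  tab <- read.delim(file.path(path, "voxels.tsv"), stringsAsFactors = FALSE)
  cohort <- align_cohort(dataset, cohort, header$subject_ids)
  idx <- match(cohort$subject_id, dataset$subject_ids)
  n <- length(idx)
  nv <- nrow(tab)
  x <- cbind((cohort$pma_scan - header$pma_mean) / header$pma_sd, cohort$sex)
  y_mean <- as.matrix(tab[, c("mean_fa", "mean_md")])
  y_sd <- as.matrix(tab[, c("sd_fa", "sd_md")])
  Ystd <- matrix(0, nv, 2 * n)
  for (v in seq_len(nv)) {
    if (tab$flag[v] != "ok") next
    Y <- dataset$values[idx, v, , drop = TRUE]
    Ystd[v, ] <- c((Y[, 1] - y_mean[v, 1]) / y_sd[v, 1],
                   (Y[, 2] - y_mean[v, 2]) / y_sd[v, 2])
  }
  cfg <- do.call(gp_config, header$config[c("restarts", "maxit", "factr",
                                            "jitter", "seed")])
  structure(list(theta = unname(as.matrix(tab[, 1:6])), y_mean = unname(y_mean),
                 y_sd = unname(y_sd), lml = tab$lml, flag = tab$flag,
                 converged = tab$converged, Ystd = Ystd, x = x,
                 D2 = as.matrix(dist(x))^2, pma_mean = header$pma_mean,
                 pma_sd = header$pma_sd, pma_range = header$pma_range,
                 subject_ids = cohort$subject_id, metrics = header$metrics,
                 config = cfg, grid_shape = dataset$grid_shape,
                 mask_index = dataset$mask_index, affine = dataset$affine),
            class = "normative_model")
}
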