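#' PMA-stratified fold assignment
#'
#' Subjects are sorted by PMA (ties broken by a seeded shuffle) and dealt
#' round-robin into k folds, so every fold covers the whole PMA range of
#' the cohort.
#'
#' @param pma Numeric PMA at scan per subject.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the tie-breaking shuffle.
#' @return Integer fold assignment in `1:k`, one per subject.
#' @export
assign_folds <- function(pma, k = 5, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  n <- length(pma)
  ord <- with_seed(seed, order(pma, runif(n)))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  if (min(tabulate(folds, k)) < 3) {
    stop("fold with fewer than 3 subjects; reduce k or enlarge the cohort")
  }
  folds
}

#' Cross-validated accuracy and held-out scores for the normative cohort
#'
#' k-fold cross-validation with PMA-stratified folds: each fold is scored
#' by a model trained on the remaining folds, yielding per-voxel,
#' per-metric mean absolute error (MAE) maps in original units, the
#' whole-mask mean MAE per metric, and held-out predictive means/SDs (and
#' hence Z-scores) for every normative subject, each of whom appears in
#' exactly one test fold.
#'
#' @param dataset A `voxel_dataset`.
#' @param cohort Covariate table; only `rows` (default: the normative
#'   group) are used.
#' @param rows Subject ids to cross-validate over.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param config A [gp_config()].
#' @param include_noise Fold noise variance into predictive SDs.
#' @param verbose Log per-fold progress.
#' @return An object of class `cv_result`: `mae` (voxels x metrics),
#'   `mean_mae` (per metric), `folds` (named by subject), `pred_mean`,
#'   `pred_sd`, `z` (subjects x voxels x metrics), `flagged` (voxels
#'   flagged in any fold).
#' @export
crossvalidate <- function(dataset, cohort, rows = NULL, k = 5, seed = 1,
                          config = gp_config(), include_noise = TRUE,
                          verbose = FALSE) {
  if (is.null(rows) && "group" %in% names(cohort)) {
    rows <- cohort$subject_id[cohort$group == "normative"]
    rows <- intersect(rows, dataset$subject_ids)
  }
  cohort <- align_cohort(dataset, cohort, rows)
  n <- nrow(cohort)
  nv <- dim(dataset$values)[2]
  folds <- assign_folds(cohort$pma_scan, k, seed)
  names(folds) <- cohort$subject_id

  pred_mean <- array(NA_real_, c(n, nv, 2),
                     dimnames = list(cohort$subject_id, NULL,
                                     dataset$metrics))
  pred_sd <- pred_mean
  flagged <- rep(FALSE, nv)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train_ids <- cohort$subject_id[-test]
    if (verbose) message("fold ", f, ": training on ", length(train_ids),
                         " subjects")
    model <- fit_all(dataset, cohort, rows = train_ids, config = config)
    flagged <- flagged | model$flag != "ok"
    p <- predict_normative(model, cohort$pma_scan[test], cohort$sex[test],
                           include_noise = include_noise)
    pred_mean[test, , ] <- p$mean
    pred_sd[test, , ] <- p$sd
  }

  idx <- match(cohort$subject_id, dataset$subject_ids)
  obs <- dataset$values[idx, , , drop = FALSE]
  err <- abs(obs - pred_mean)
  mae <- apply(err, c(2, 3), mean)
  z <- (obs - pred_mean) / pred_sd
  structure(list(mae = mae, mean_mae = colMeans(mae, na.rm = TRUE),
                 folds = folds, pred_mean = pred_mean, pred_sd = pred_sd,
                 z = z, flagged = flagged, include_noise = include_noise,
                 subject_ids = cohort$subject_id),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", length(x$folds), "subjects,", max(x$folds), "folds\n")
  cat("  whole-mask mean MAE:",
      paste(names(x$mean_mae), signif(x$mean_mae, 3), collapse = ", "), "\n")
  invisible(x)
}
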