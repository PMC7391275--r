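#' Z-score deviation maps for a set of subjects
#'
#' Z = (observed - predictive mean) / predictive SD per voxel and metric.
#' Holdout subjects are scored against a model trained on the full
#' normative cohort; normative subjects themselves should be scored from
#' their cross-validation held-out predictions ([zscore_from_cv()]) so that
#' no subject is scored by a model trained on itself. Voxels whose model is
#' flagged degenerate yield NA, never silent zeros.
#'
#' @param model A `normative_model`.
#' @param dataset A `voxel_dataset` holding the subjects to score.
#' @param cohort Covariate table covering those subjects.
#' @param rows Subject ids to score (default: all subjects of `dataset`).
#' @param include_noise Fold noise variance into the predictive SD
#'   (default TRUE; the convention under which null Z-scores are standard
#'   normal).
#' @return An object of class `deviation_maps`: `z` (subjects x voxels x
#'   metrics), `valid` (voxels with an unflagged model), subject ids.
#' @export
zscore_maps <- function(model, dataset, cohort, rows = NULL,
                        include_noise = TRUE) {
  rows <- rows %||% dataset$subject_ids
  cohort <- align_cohort(dataset, cohort, rows)
  idx <- match(cohort$subject_id, dataset$subject_ids)
  p <- predict_normative(model, cohort$pma_scan, cohort$sex,
                         include_noise = include_noise)
  obs <- dataset$values[idx, , , drop = FALSE]
  z <- (obs - p$mean) / p$sd
  dimnames(z)[[1]] <- cohort$subject_id
  structure(list(z = z, valid = model$flag == "ok",
                 subject_ids = cohort$subject_id,
                 include_noise = include_noise, threshold = NULL),
            class = "deviation_maps")
}

#' Deviation maps from cross-validation held-out predictions
#'
#' @param cv A `cv_result` from [crossvalidate()].
#' @param dataset The dataset the CV was run on.
#' @return A `deviation_maps` for the cross-validated (normative) subjects.
#' @export
zscore_from_cv <- function(cv, dataset) {
  structure(list(z = cv$z, valid = !cv$flagged, subject_ids = cv$subject_ids,
                 include_noise = cv$include_noise, threshold = NULL),
            class = "deviation_maps")
}

#' Threshold Z maps into directional extreme-deviation masks
#'
#' Strict inequalities: the positive mask is Z > t, the negative mask
#' Z < -t, so a voxel at exactly |Z| = t belongs to neither. NA voxels
#' (degenerate models) are in neither mask.
#'
#' @param dev A `deviation_maps`.
#' @param threshold Positive deviation threshold (default 3.1).
#' @return `dev` with `pos` and `neg` logical arrays (subjects x voxels x
#'   metrics) and the threshold recorded. The four directional masks per
#'   subject are `pos[, , "FA"]` (FA+), `neg[, , "FA"]` (FA-),
#'   `pos[, , "MD"]` (MD+), `neg[, , "MD"]` (MD-).
#' @export
threshold_extremes <- function(dev, threshold = 3.1) {
  stopifnot(inherits(dev, "deviation_maps"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  dev$pos <- !is.na(dev$z) & dev$z > threshold
  dev$neg <- !is.na(dev$z) & dev$z < -threshold
  dev$threshold <- threshold
  dev
}

#' @export
print.deviation_maps <- function(x, ...) {
  cat("deviation_maps:", dim(x$z)[1], "subjects,", dim(x$z)[2], "voxels,",
      sum(!x$valid), "excluded voxel(s)\n")
  if (!is.null(x$threshold)) {
    cat("  thresholded at |Z| >", x$threshold, "\n")
  }
  invisible(x)
}

#' Voxel-wise percentage overlap of extreme deviations
#'
#' For one metric and direction, the per-voxel percentage of subjects in
#' the group with an extreme deviation: 100 x (number of subjects with
#' |Z| > t in that direction) / (number of subjects). Voxels excluded by a
#' degenerate model are NA.
#'
#' @param dev A thresholded `deviation_maps`.
#' @param metric `"FA"` or `"MD"`.
#' @param direction `"pos"` or `"neg"`.
#' @return Numeric vector over in-mask voxels, values in \[0, 100\], with
#'   attributes `n_subjects`, `metric`, `direction`.
#' @export
overlap_map <- function(dev, metric = "FA", direction = c("pos", "neg")) {
  direction <- match.arg(direction)
  if (is.null(dev$threshold)) stop("deviation maps have not been thresholded")
  masks <- dev[[direction]][, , metric, drop = FALSE]
  n <- dim(masks)[1]
  if (n == 0) stop("empty group: no subjects to overlap")
  pct <- 100 * colMeans(masks[, , 1, drop = FALSE])[, 1]
  pct[!dev$valid] <- NA_real_
  attr(pct, "n_subjects") <- n
  attr(pct, "metric") <- metric
  attr(pct, "direction") <- direction
  pct
}

#' Consistency mask from an overlap map
#'
#' Voxels where the percentage of subjects with extreme deviations is
#' strictly greater than `percent` (default 4, i.e. more than 4% of the
#' group).
#'
#' @param overlap A vector from [overlap_map()].
#' @param percent Consistency threshold in percent, in (0, 100).
#' @return Logical vector over in-mask voxels (NA overlap voxels are
#'   FALSE).
#' @export
consistency_mask <- function(overlap, percent = 4) {
  if (!is.numeric(percent) || percent <= 0 || percent >= 100) {
    stop("percent must lie strictly between 0 and 100")
  }
  !is.na(overlap) & overlap > percent
}

#' Write deviation maps and overlap maps as NIfTI
#'
#' Z maps are written as 32-bit float, directional masks as unsigned
#' 8-bit, with filenames encoding subject, metric and direction, under the
#' affine of the input grid.
#'
#' @param dev A thresholded `deviation_maps`.
#' @param dataset The `voxel_dataset` providing grid geometry.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_deviation_maps <- function(dev, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- abs(diag(dataset$affine)[1:3])
  paths <- character(0)
  for (s in seq_along(dev$subject_ids)) {
    for (m in dimnames(dev$z)[[3]]) {
      vol <- array(0, dataset$grid_shape)
      vol[dataset$mask_index] <- ifelse(is.na(dev$z[s, , m]), 0,
                                        dev$z[s, , m])
      p <- file.path(dir, sprintf("%s_%s_z.nii.gz", dev$subject_ids[s],
                                  tolower(m)))
      RNifti::writeNifti(RNifti::asNifti(vol, pixdim = pix), p,
                         datatype = "float")
      paths <- c(paths, p)
      for (d in c("pos", "neg")) {
        vol <- array(0L, dataset$grid_shape)
        vol[dataset$mask_index] <- as.integer(dev[[d]][s, , m])
        p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", dev$subject_ids[s],
                                    tolower(m), d))
        RNifti::writeNifti(RNifti::asNifti(vol, pixdim = pix), p,
                           datatype = "uint8")
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
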