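#' Whole-brain atypicality indices
#'
#' Reduces each subject's directional extreme-deviation masks to four
#' whole-brain indices -- FA+, FA-, MD+ and MD- -- each the percentage of
#' valid intracerebral voxels with an extreme deviation in that direction
#' for that metric. The denominator is the number of in-mask voxels minus
#' the voxels excluded by degenerate models, reported per subject.
#'
#' @param dev A thresholded `deviation_maps` (see [threshold_extremes()]).
#' @return A data.frame of class `atypicality_record`: one row per subject
#'   with columns `subject_id`, `fa_plus`, `fa_minus`, `md_plus`,
#'   `md_minus` (percent), `n_mask_voxels`, `n_excluded_voxels`.
#' @export
atypicality_index <- function(dev) {
  stopifnot(inherits(dev, "deviation_maps"))
  if (is.null(dev$threshold)) stop("deviation maps have not been thresholded")
  nv <- dim(dev$z)[2]
  if (nv == 0) stop("empty intracerebral mask")
  valid <- dev$valid
  denom <- sum(valid)
  if (denom == 0) stop("empty intracerebral mask: all voxels excluded")
  count <- function(arr, m) rowSums(arr[, valid, m, drop = FALSE])
  out <- data.frame(
    subject_id = dev$subject_ids,
    fa_plus = 100 * count(dev$pos, "FA") / denom,
    fa_minus = 100 * count(dev$neg, "FA") / denom,
    md_plus = 100 * count(dev$pos, "MD") / denom,
    md_minus = 100 * count(dev$neg, "MD") / denom,
    n_mask_voxels = denom,
    n_excluded_voxels = nv - denom,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("atypicality_record", "data.frame")
  out
}

#' Join atypicality records to the cohort covariates
#'
#' @param records An `atypicality_record` data.frame (rows may come from
#'   several scoring runs, e.g. CV-scored normative subjects plus
#'   full-model-scored holdout subjects).
#' @param cohort Cohort covariate table; every record's subject must be
#'   present, and the output preserves the cohort table's row order
#'   restricted to scored subjects.
#' @return A data.frame ready for the statistical battery: covariates plus
#'   the four indices and voxel counts.
#' @export
atypicality_table <- function(records, cohort) {
  if (nrow(records) < 1) stop("at least one atypicality record is required")
  if (anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id in atypicality records: ",
         paste(unique(records$subject_id[duplicated(records$subject_id)]),
               collapse = ", "))
  }
  unknown <- setdiff(records$subject_id, cohort$subject_id)
  if (length(unknown)) {
    stop("record(s) for unknown subject(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  ids <- cohort$subject_id[cohort$subject_id %in% records$subject_id]
  merged <- cbind(cohort[match(ids, cohort$subject_id), , drop = FALSE],
                  records[match(ids, records$subject_id),
                          setdiff(names(records), "subject_id"),
                          drop = FALSE])
  rownames(merged) <- NULL
  merged
}

#' Write / read an atypicality table as TSV
#'
#' @param table A joined atypicality table.
#' @param path TSV path.
#' @return `write_atypicality` invisibly returns `path`;
#'   `read_atypicality` returns the data.frame.
#' @export
write_atypicality <- function(table, path) {
  write.table(format(table, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atypicality
#' @export
read_atypicality <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
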