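#' Specify a synthetic cohort
#'
#' Collects every tunable of the synthetic-data generator into a validated
#' specification object. The defaults emulate the design of a neonatal
#' normative-modelling study: a large term-born normative group and a smaller
#' preterm ("atypical") group scanned between 37 and 45 weeks postmenstrual
#' age (PMA), with per-voxel FA increasing and MD decreasing with PMA, and
#' focal lesion-like deviations injected only in the atypical group.
#'
#' @param n_normative Number of normative (term-born) subjects; at least 20.
#' @param n_atypical Number of atypical (preterm-born) subjects; may be 0.
#' @param pma_range Numeric length-2, PMA-at-scan range in weeks (low < high).
#' @param grid_shape Integer length-3 voxel grid; every axis at least 4.
#' @param seed Integer seed; all generator output is a pure function of the
#'   spec including this seed.
#' @param noise_sd_fa Subject-level i.i.d. Gaussian noise SD for FA
#'   (unitless).
#' @param noise_sd_md Noise SD for MD, in micrometers^2/ms.
#' @param lesion_count_range Integer length-2 (min, max) lesion clusters per
#'   atypical subject; `c(0, 0)` disables lesions (a null cohort).
#' @param lesion_effect_sd_multiplier Lesion offset magnitude in units of the
#'   subject-level noise SD of each metric. Lesions raise MD and lower FA.
#' @param lesion_radius_range Lesion sphere radius range in voxels.
#' @param smooth_sigma Gaussian smoothing SD (voxels) applied to the random
#'   intercept/slope fields so neighbouring voxels are spatially correlated.
#' @param mask_radius_frac Radius of the spherical intracerebral mask as a
#'   fraction of the smallest grid axis.
#' @param lesion_overlap_bound Declared upper bound on the median pairwise
#'   Jaccard overlap of atypical lesion masks (a documented property of the
#'   generator, checked by its test suite, modelling the low spatial overlap
#'   of deviations between individual infants).
#' @param reference_pma PMA (weeks) at which per-voxel intercepts are
#'   expressed; defaults to 40, the middle of the scan window.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normative = 270, n_atypical = 82,
                        pma_range = c(37, 45), grid_shape = c(20, 20, 20),
                        seed = 1, noise_sd_fa = 0.025, noise_sd_md = 0.07,
                        lesion_count_range = c(1, 4),
                        lesion_effect_sd_multiplier = 5,
                        lesion_radius_range = c(1.5, 3),
                        smooth_sigma = 1.5, mask_radius_frac = 0.4,
                        lesion_overlap_bound = 0.2, reference_pma = 40) {
  spec <- list(n_normative = as.integer(n_normative),
               n_atypical = as.integer(n_atypical),
               pma_range = as.numeric(pma_range),
               grid_shape = as.integer(grid_shape), seed = as.integer(seed),
               noise_sd_fa = noise_sd_fa, noise_sd_md = noise_sd_md,
               lesion_count_range = as.integer(lesion_count_range),
               lesion_effect_sd_multiplier = lesion_effect_sd_multiplier,
               lesion_radius_range = as.numeric(lesion_radius_range),
               smooth_sigma = smooth_sigma,
               mask_radius_frac = mask_radius_frac,
               lesion_overlap_bound = lesion_overlap_bound,
               reference_pma = reference_pma)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg) {
    stop("invalid cohort spec: field '", field, "' ", msg, call. = FALSE)
  }
  if (is.na(spec$n_normative) || spec$n_normative < 20) {
    fail("n_normative", "must be at least 20")
  }
  if (is.na(spec$n_atypical) || spec$n_atypical < 0) {
    fail("n_atypical", "must be non-negative")
  }
  if (length(spec$pma_range) != 2 || spec$pma_range[1] >= spec$pma_range[2]) {
    fail("pma_range", "must satisfy low < high")
  }
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 4)) {
    fail("grid_shape", "must have three axes all >= 4")
  }
  if (spec$noise_sd_fa <= 0) fail("noise_sd_fa", "must be positive")
  if (spec$noise_sd_md <= 0) fail("noise_sd_md", "must be positive")
  if (length(spec$lesion_count_range) != 2 ||
      any(spec$lesion_count_range < 0) ||
      spec$lesion_count_range[1] > spec$lesion_count_range[2]) {
    fail("lesion_count_range", "must be 0 <= min <= max")
  }
  if (any(spec$lesion_radius_range <= 0) ||
      spec$lesion_radius_range[1] > spec$lesion_radius_range[2]) {
    fail("lesion_radius_range", "must be positive with min <= max")
  }
  if (spec$mask_radius_frac <= 0 || spec$mask_radius_frac > 0.5) {
    fail("mask_radius_frac", "must lie in (0, 0.5]")
  }
  invisible(spec)
}

# Separable 3D Gaussian smoothing with reflecting boundaries.
smooth_field3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    idx <- seq_len(d[1])
    out <- matrix(0, d[1], ncol(m))
    for (j in seq_along(k)) {
      off <- idx + (j - half - 1L)
      # reflecting boundary, valid for kernels wider than the axis
      r <- abs(off - 1L) %% (2L * (d[1] - 1L))
      off <- 1L + pmin(r, 2L * (d[1] - 1L) - r)
      out <- out + k[j] * m[off, , drop = FALSE]
    }
    aperm(array(out, d), order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

# Smoothed random field over the grid, rank-uniformized so that the in-mask
# marginal distribution is uniform on [lo, hi] (stable across grid sizes)
# while the smoothing keeps neighbouring voxels correlated.
random_field <- function(grid_shape, sigma, lo, hi, mask_index) {
  f <- smooth_field3d(array(rnorm(prod(grid_shape)), grid_shape), sigma)
  v <- f[mask_index]
  u <- rank(v, ties.method = "average") / (length(v) + 1)
  lo + u * (hi - lo)
}

sphere_index <- function(grid_shape, centre, radius) {
  cx <- slice.index(array(0, grid_shape), 1) - centre[1]
  cy <- slice.index(array(0, grid_shape), 2) - centre[2]
  cz <- slice.index(array(0, grid_shape), 3) - centre[3]
  which(cx^2 + cy^2 + cz^2 <= radius^2)
}

#' Generate a synthetic cohort table and its ground truth
#'
#' Draws per-subject covariates and the latent voxel-wise "developmental
#' plane" (per-voxel FA/MD intercepts at the reference PMA and linear PMA
#' slopes, plus constant sex offsets), together with per-subject lesion
#' masks for the atypical group. Intercept and slope fields are smoothed
#' random fields so neighbouring voxels are correlated, as in real parameter
#' maps. Lesions are contiguous spheres with random centres inside the
#' intracerebral mask; each raises MD and lowers FA by
#' `lesion_effect_sd_multiplier` noise SDs.
#'
#' Outcome scores (BSID-III-like composites, mean 100 / SD 15 in the
#' normative group) are generated with a negative linear dependence on each
#' atypical subject's total lesion volume fraction, so that downstream
#' brain-behaviour correlation tests have a known sign; normative outcomes
#' are independent noise.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `table` (data.frame, one row per subject:
#'   `subject_id`, `group`, `pma_scan`, `ga_birth`, `sex` (female = 0,
#'   male = 1), `motion`, `imd`, `outcome_cognitive`, `outcome_language`,
#'   `outcome_motor`) and `truth` (class `cohort_truth`: mask, per-voxel
#'   intercept/slope fields, sex offsets, lesion index sets and offsets,
#'   per-subject lesion volume fractions).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    gs <- spec$grid_shape
    centre <- (gs + 1) / 2
    mask_radius <- spec$mask_radius_frac * min(gs)
    mask_index <- sphere_index(gs, centre, mask_radius)
    mask <- array(FALSE, gs)
    mask[mask_index] <- TRUE
    nv <- length(mask_index)

    truth <- list(
      mask = mask, mask_index = mask_index, grid_shape = gs,
      reference_pma = spec$reference_pma,
      fa_intercept = random_field(gs, spec$smooth_sigma, 0.15, 0.45, mask_index),
      fa_slope = random_field(gs, spec$smooth_sigma, 0.002, 0.020, mask_index),
      md_intercept = random_field(gs, spec$smooth_sigma, 0.80, 1.40, mask_index),
      md_slope = random_field(gs, spec$smooth_sigma, -0.055, -0.008, mask_index),
      fa_sex_offset = 0.005, md_sex_offset = -0.010)

    n <- spec$n_normative + spec$n_atypical
    group <- rep(c("normative", "atypical"),
                 c(spec$n_normative, spec$n_atypical))
    subject_id <- sprintf("sub-%04d", seq_len(n))
    pma_scan <- runif(n, spec$pma_range[1], spec$pma_range[2])
    ga_birth <- ifelse(group == "normative", runif(n, 37, 42),
                       pmin(36.9, pmax(24, rnorm(n, 32, 3))))
    sex <- rbinom(n, 1, 0.51)
    motion <- exp(rnorm(n, 0, 0.3))
    imd <- pmin(80, rgamma(n, shape = 2,
                           scale = ifelse(group == "normative", 13.5, 8.7)))

    # lesion clusters: sphere centres drawn uniformly over mask voxels;
    # the cluster is the sphere's intersection with the mask
    lesions <- list()
    lesion_load <- setNames(numeric(n), subject_id)
    atypical_rows <- which(group == "atypical")
    for (i in atypical_rows) {
      k <- if (spec$lesion_count_range[2] == 0) 0L else
        sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1)
      vox <- integer(0)
      if (k > 0) {
        for (l in seq_len(k)) {
          ctr_lin <- mask_index[sample.int(nv, 1)]
          ctr <- arrayInd(ctr_lin, gs)[1, ]
          r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
          vox <- union(vox, intersect(sphere_index(gs, ctr, r), mask_index))
        }
      }
      lesions[[subject_id[i]]] <- list(
        voxels = match(vox, mask_index),
        fa_offset = -spec$lesion_effect_sd_multiplier * spec$noise_sd_fa,
        md_offset = +spec$lesion_effect_sd_multiplier * spec$noise_sd_md)
      lesion_load[i] <- 100 * length(vox) / nv
    }
    truth$lesions <- lesions
    truth$lesion_load <- lesion_load
    class(truth) <- "cohort_truth"

    outcome <- function() {
      ifelse(group == "normative", rnorm(n, 100, 15),
             103 - 2.0 * lesion_load + rnorm(n, 0, 6))
    }
    table <- data.frame(subject_id = subject_id, group = group,
                        pma_scan = pma_scan, ga_birth = ga_birth, sex = sex,
                        motion = motion, imd = imd,
                        outcome_cognitive = outcome(),
                        outcome_language = outcome(),
                        outcome_motor = outcome(),
                        stringsAsFactors = FALSE)
    list(table = table, truth = truth)
  })
}

#' Generate scalar maps for a cohort
#'
#' Realises the voxel values implied by the ground truth: for each subject
#' and mask voxel, value = intercept + slope x (PMA - reference PMA) +
#' sex offset x sex + i.i.d. Gaussian noise, plus the subject's signed
#' lesion offset inside lesion voxels. FA is clipped to \[0, 1\] and MD
#' floored at a small positive value; clipping events are counted and
#' reported via the `n_clipped` element.
#'
#' @param table,truth The pair returned by [generate_cohort()].
#' @param spec The same [cohort_spec()] used to generate them.
#' @return A `voxel_dataset`: masked subject x voxel x metric values plus
#'   grid geometry.
#' @export
generate_scalar_maps <- function(table, truth, spec) {
  validate_cohort_spec(spec)
  if (!identical(names(truth$lesion_load), table$subject_id)) {
    stop("cohort table and ground truth describe different subject sets")
  }
  n <- nrow(table)
  nv <- length(truth$mask_index)
  with_seed(derive_seed(spec$seed, 7919), {
    dpma <- table$pma_scan - truth$reference_pma
    fa <- outer(rep(1, n), truth$fa_intercept) + outer(dpma, truth$fa_slope) +
      truth$fa_sex_offset * table$sex +
      matrix(rnorm(n * nv, 0, spec$noise_sd_fa), n, nv)
    md <- outer(rep(1, n), truth$md_intercept) + outer(dpma, truth$md_slope) +
      truth$md_sex_offset * table$sex +
      matrix(rnorm(n * nv, 0, spec$noise_sd_md), n, nv)
    for (sid in names(truth$lesions)) {
      les <- truth$lesions[[sid]]
      if (length(les$voxels) == 0) next
      i <- match(sid, table$subject_id)
      fa[i, les$voxels] <- fa[i, les$voxels] + les$fa_offset
      md[i, les$voxels] <- md[i, les$voxels] + les$md_offset
    }
    n_clipped <- c(FA = sum(fa < 0 | fa > 1), MD = sum(md < 1e-4))
    fa <- pmin(pmax(fa, 0), 1)
    md <- pmax(md, 1e-4)
    values <- array(c(fa, md), c(n, nv, 2),
                    dimnames = list(table$subject_id, NULL, c("FA", "MD")))
    voxel_dataset(values, truth$mask, affine = diag(c(1.5, 1.5, 1.5, 1)),
                  n_clipped = n_clipped)
  })
}

#' Construct a voxel dataset
#'
#' The in-memory container for masked 4D scalar maps: a subjects x in-mask
#' voxels x metrics array together with the grid geometry needed to
#' reconstruct full volumes.
#'
#' @param values Numeric array, subjects x in-mask voxels x metrics, with
#'   subject ids and metric names as dimnames.
#' @param mask Logical 3D array; `sum(mask)` must equal `dim(values)[2]`.
#' @param affine 4x4 voxel-to-world matrix, propagated unchanged to outputs.
#' @param n_clipped Optional named count of clipped values per metric.
#' @return An object of class `voxel_dataset`.
#' @export
voxel_dataset <- function(values, mask, affine = diag(c(1.5, 1.5, 1.5, 1)),
                          n_clipped = NULL) {
  stopifnot(length(dim(values)) == 3, is.logical(mask),
            sum(mask) == dim(values)[2])
  structure(list(values = values, mask = mask, mask_index = which(mask),
                 grid_shape = dim(mask), affine = affine,
                 metrics = dimnames(values)[[3]],
                 subject_ids = dimnames(values)[[1]],
                 n_clipped = n_clipped),
            class = "voxel_dataset")
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat("voxel_dataset:", dim(x$values)[1], "subjects,", dim(x$values)[2],
      "in-mask voxels,", paste(x$metrics, collapse = "/"), "on grid",
      paste(x$grid_shape, collapse = "x"), "\n")
  if (!is.null(x$n_clipped) && any(x$n_clipped > 0)) {
    cat("  clipped values:", paste(names(x$n_clipped), x$n_clipped,
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

# Rebuild a full 4D grid array (grid x subjects) from masked values for one
# metric, with 0 outside the mask.
unmask_volumes <- function(dataset, metric) {
  n <- dim(dataset$values)[1]
  out <- array(0, c(dataset$grid_shape, n))
  stride <- prod(dataset$grid_shape)
  for (i in seq_len(n)) {
    out[dataset$mask_index + (i - 1) * stride] <- dataset$values[i, , metric]
  }
  out
}

#' Write a dataset to a directory as NIfTI + TSV
#'
#' Writes one 4D NIfTI per metric (4th axis = subjects, ordered as the
#' covariate table rows), the binary intracerebral mask, the covariate table
#' as TSV, and (optionally) a ground-truth sidecar in JSON sufficient to
#' reconstruct the generating parameters.
#'
#' @param dataset A `voxel_dataset`.
#' @param table The cohort covariate table aligned with `dataset`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `cohort_truth` to serialise alongside.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, table, dir, truth = NULL) {
  if (!identical(dataset$subject_ids, table$subject_id)) {
    stop("dataset subject order does not match covariate table")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pix <- abs(diag(dataset$affine)[1:3])
  paths <- c()
  for (metric in dataset$metrics) {
    p <- file.path(dir, paste0(tolower(metric), ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(unmask_volumes(dataset, metric),
                                       pixdim = pix), p)
    paths[metric] <- p
  }
  p <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(dataset$mask),
                                           dataset$grid_shape), pixdim = pix), p)
  paths["mask"] <- p
  p <- file.path(dir, "covariates.tsv")
  write.table(table, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["covariates"] <- p
  if (!is.null(truth)) {
    p <- file.path(dir, "ground_truth.json")
    tr <- unclass(truth)
    tr$mask <- NULL  # carried by mask.nii.gz
    tr$mask_index <- as.integer(tr$mask_index)
    jsonlite::write_json(tr, p, auto_unbox = TRUE, digits = NA)
    paths["truth"] <- p
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `fa.nii.gz`, `md.nii.gz`, `mask.nii.gz`
#'   and `covariates.tsv` (plus optionally `ground_truth.json`).
#' @return A list with `dataset`, `table` and (if present) `truth`.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("fa.nii.gz", "md.nii.gz", "mask.nii.gz",
                           "covariates.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  mask_img <- RNifti::readNifti(need[3])
  mask <- array(as.vector(mask_img) > 0.5, dim(mask_img))
  mask_index <- which(mask)
  table <- read.delim(need[4], stringsAsFactors = FALSE)
  n <- nrow(table)
  grab <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) != 4 || dim(arr)[4] != n) {
      stop("volume ", path, " has 4th-axis length ", dim(arr)[4],
           " but covariate table has ", n, " rows")
    }
    stride <- prod(dim(arr)[1:3])
    t(vapply(seq_len(n),
             function(i) arr[mask_index + (i - 1) * stride],
             numeric(length(mask_index))))
  }
  fa <- grab(need[1])
  md <- grab(need[2])
  values <- array(c(fa, md), c(n, length(mask_index), 2),
                  dimnames = list(table$subject_id, NULL, c("FA", "MD")))
  affine <- structure(RNifti::xform(mask_img), class = NULL)
  affine <- rbind(cbind(affine[1:3, 1:3], affine[1:3, 4]), c(0, 0, 0, 1))
  out <- list(dataset = voxel_dataset(values, mask, affine = affine),
              table = table)
  tp <- file.path(dir, "ground_truth.json")
  if (file.exists(tp)) {
    tr <- jsonlite::read_json(tp, simplifyVector = TRUE)
    tr$mask <- mask
    tr$mask_index <- mask_index
    tr$grid_shape <- dim(mask)
    tr$lesions <- lapply(tr$lesions, function(l) {
      l$voxels <- as.integer(l$voxels)
      l
    })
    class(tr) <- "cohort_truth"
    out$truth <- tr
  }
  out
}
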