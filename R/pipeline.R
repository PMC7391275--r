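#' Pipeline run configuration
#'
#' Collects every pipeline tunable with defaults matching the analysis
#' conventions used throughout the package: |Z| > 3.1 extreme threshold,
#' 4% consistency rule, 5 PMA-stratified CV folds, 1000/100 bootstrap
#' replications and alpha = 0.05. The configuration round-trips losslessly
#' through YAML.
#'
#' @param input_dir Directory with `fa.nii.gz`, `md.nii.gz`, `mask.nii.gz`
#'   and `covariates.tsv`; `NULL` to simulate a cohort instead.
#' @param out_dir Output directory for all stages.
#' @param simulate A [cohort_spec()] (or argument list for one) used when
#'   `input_dir` is NULL.
#' @param threshold Extreme-deviation |Z| threshold.
#' @param consistency_percent Group-consistency percentage threshold.
#' @param folds Cross-validation folds.
#' @param bootstrap_reps,prediction_resamples Bootstrap sizes for the
#'   regression stage.
#' @param alpha Family-wise error level.
#' @param include_noise Fold noise variance into predictive SDs.
#' @param restarts,maxit Optimizer settings (see [gp_config()]).
#' @param seed Global seed for simulation, fold assignment, optimizer
#'   restarts and bootstraps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = "voxnorm_run",
                       simulate = NULL, threshold = 3.1,
                       consistency_percent = 4, folds = 5,
                       bootstrap_reps = 1000, prediction_resamples = 100,
                       alpha = 0.05, include_noise = TRUE, restarts = 3,
                       maxit = 80, seed = 1) {
  if (!is.null(simulate) && !inherits(simulate, "cohort_spec")) {
    simulate <- do.call(cohort_spec, as.list(simulate))
  }
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 simulate = simulate, threshold = threshold,
                 consistency_percent = consistency_percent,
                 folds = as.integer(folds),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 prediction_resamples = as.integer(prediction_resamples),
                 alpha = alpha, include_noise = include_noise,
                 restarts = as.integer(restarts), maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$simulate)) x$simulate <- unclass(x$simulate)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate)) x$simulate <- do.call(cohort_spec, x$simulate)
  do.call(run_config, x)
}

#' Validate pipeline inputs before computing
#'
#' Checks that all input files exist, that metric and mask grids agree,
#' that the covariate table is complete and aligned with the image 4th
#' axis, that PMA values are plausible (warning outside 30-50 weeks), that
#' FA lies in \[0, 1\], and that MD is on the micrometer^2/ms scale (values
#' around 1e-3 suggest mm^2/s and trigger a unit warning).
#'
#' @param input_dir Directory of inputs as for [run_config()].
#' @param strict Stop with an itemized error when hard problems are found?
#' @return A list of class `validation_report`: `errors`, `warnings`,
#'   `ok`.
#' @export
validate_inputs <- function(input_dir, strict = TRUE) {
  errors <- character(0)
  warnings <- character(0)
  need <- file.path(input_dir, c("fa.nii.gz", "md.nii.gz", "mask.nii.gz",
                                 "covariates.tsv"))
  names(need) <- c("fa", "md", "mask", "covariates")
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    errors <- c(errors, paste0("missing input file: ", missing))
  } else {
    hdr <- lapply(need[1:3], RNifti::niftiHeader)
    gdim <- function(h) h$dim[seq_len(3) + 1]
    if (!identical(gdim(hdr$fa), gdim(hdr$mask)) ||
        !identical(gdim(hdr$md), gdim(hdr$mask))) {
      errors <- c(errors, "grid mismatch: metric volumes and mask differ in shape")
    }
    tab <- read.delim(need["covariates"], stringsAsFactors = FALSE)
    req <- c("subject_id", "group", "pma_scan", "ga_birth", "sex")
    gone <- setdiff(req, names(tab))
    if (length(gone)) {
      errors <- c(errors, paste0("covariate column missing: ", gone))
    }
    n_img <- hdr$fa$dim[5]
    if (!length(gone) && n_img != nrow(tab)) {
      errors <- c(errors,
                  sprintf("covariate rows (%d) do not match image volumes (%d): a covariate row is missing or extra",
                          nrow(tab), n_img))
    }
    if ("pma_scan" %in% names(tab)) {
      if (anyNA(tab$pma_scan)) {
        errors <- c(errors, "missing pma_scan value(s)")
      } else if (any(tab$pma_scan < 30 | tab$pma_scan > 50)) {
        warnings <- c(warnings, "pma_scan outside 30-50 weeks for some subjects")
      }
    }
    if (!length(errors)) {
      mask <- RNifti::readNifti(need["mask"])
      midx <- which(array(as.vector(mask) > 0.5, dim(mask)))
      fa1 <- RNifti::readNifti(need["fa"])
      fa_vals <- as.vector(fa1)[midx]  # first volume's in-mask values
      if (any(fa_vals < -1e-6 | fa_vals > 1 + 1e-6)) {
        errors <- c(errors, "FA values outside [0, 1]")
      }
      md1 <- RNifti::readNifti(need["md"])
      md_med <- median(as.vector(md1)[midx])
      if (is.finite(md_med) && md_med < 0.01) {
        warnings <- c(warnings,
                      "MD values are ~1e-3: volume appears to be in mm^2/s; rescale to micrometer^2/ms (x1000)")
      }
    }
  }
  report <- structure(list(errors = errors, warnings = warnings,
                           ok = length(errors) == 0),
                      class = "validation_report")
  for (w in warnings) warning(w, call. = FALSE)
  if (strict && !report$ok) {
    stop("input validation failed:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full pipeline
#'
#' Sequences simulate (optional) -> validate -> fit -> cross-validate ->
#' score -> overlap -> atypicality -> stats, writing each stage's outputs
#' under `out_dir` together with a manifest (config echo, subject
#' id-to-index map, per-stage runtimes, output checksums). With
#' `resume = TRUE`, stages whose outputs already exist are skipped and
#' later stages recomputed from them. Identical config and seed produce
#' byte-identical report tables.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage outputs?
#' @param verbose Log stage progress.
#' @return Invisibly, a list with `out_dir`, the `manifest`, and the key
#'   result objects (`atypicality`, `battery`, `cv`).
#' @export
run_pipeline <- function(config, resume = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- list(config = unclass(config), stages = list())
  if (!is.null(manifest$config$simulate)) {
    manifest$config$simulate <- unclass(manifest$config$simulate)
  }
  say <- function(...) if (verbose) message(...)
  timed <- function(stage, code) {
    t0 <- Sys.time()
    res <- code
    manifest$stages[[stage]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  gpcfg <- gp_config(restarts = config$restarts, maxit = config$maxit,
                     seed = config$seed)

  # -- simulate or locate inputs ------------------------------------------
  data_dir <- config$input_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(out, "data")
    if (!(resume && file.exists(file.path(data_dir, "covariates.tsv")))) {
      say("stage simulate")
      timed("simulate", {
        spec <- config$simulate %||% cohort_spec(seed = config$seed)
        coh <- generate_cohort(spec)
        ds <- generate_scalar_maps(coh$table, coh$truth, spec)
        write_dataset(ds, coh$table, data_dir, truth = coh$truth)
      })
    }
  }

  say("stage validate")
  timed("validate", validate_inputs(data_dir, strict = TRUE))
  inp <- read_dataset(data_dir)
  dataset <- inp$dataset
  table <- inp$table
  manifest$subjects <- setNames(as.list(seq_along(dataset$subject_ids)),
                                dataset$subject_ids)

  norm_ids <- table$subject_id[table$group == "normative"]
  atyp_ids <- table$subject_id[table$group == "atypical"]

  # -- fit ----------------------------------------------------------------
  model_dir <- file.path(out, "model")
  if (resume && file.exists(file.path(model_dir, "voxels.tsv"))) {
    model <- read_model_store(model_dir, dataset, table)
  } else {
    say("stage fit (", length(norm_ids), " normative subjects, ",
        dim(dataset$values)[2], " voxels)")
    model <- timed("fit", fit_all(dataset, table, rows = norm_ids,
                                  config = gpcfg, verbose = verbose))
    write_model_store(model, model_dir)
  }

  # -- cross-validate -----------------------------------------------------
  cv_path <- file.path(out, "cv.rds")
  if (resume && file.exists(cv_path)) {
    cv <- readRDS(cv_path)
  } else {
    say("stage crossvalidate")
    cv <- timed("crossvalidate",
                crossvalidate(dataset, table, rows = norm_ids,
                              k = config$folds, seed = config$seed,
                              config = gpcfg,
                              include_noise = config$include_noise))
    saveRDS(cv, cv_path)
    mae_tab <- data.frame(voxel = seq_len(nrow(cv$mae)), cv$mae)
    write.table(format(mae_tab, digits = 17), file.path(out, "cv_mae.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- score --------------------------------------------------------------
  say("stage score")
  dev_norm <- threshold_extremes(zscore_from_cv(cv, dataset),
                                 config$threshold)
  records <- atypicality_index(dev_norm)
  dev_atyp <- NULL
  if (length(atyp_ids)) {
    dev_atyp <- timed("score", {
      d <- zscore_maps(model, dataset, table, rows = atyp_ids,
                       include_noise = config$include_noise)
      threshold_extremes(d, config$threshold)
    })
    records <- rbind(records, atypicality_index(dev_atyp))
  }

  # -- overlap ------------------------------------------------------------
  say("stage overlap")
  timed("overlap", {
    pix <- abs(diag(dataset$affine)[1:3])
    for (grp in c("normative", "atypical")) {
      dev <- if (grp == "normative") dev_norm else dev_atyp
      if (is.null(dev)) next
      for (m in dataset$metrics) {
        for (d in c("pos", "neg")) {
          ov <- overlap_map(dev, m, d)
          cm <- consistency_mask(ov, config$consistency_percent)
          vol <- array(0, dataset$grid_shape)
          vol[dataset$mask_index] <- ifelse(is.na(ov), 0, ov)
          RNifti::writeNifti(
            RNifti::asNifti(vol, pixdim = pix),
            file.path(out, sprintf("overlap_%s_%s_%s.nii.gz", grp,
                                   tolower(m), d)))
          vol <- array(0L, dataset$grid_shape)
          vol[dataset$mask_index] <- as.integer(cm)
          RNifti::writeNifti(
            RNifti::asNifti(vol, pixdim = pix),
            file.path(out, sprintf("consistency_%s_%s_%s.nii.gz", grp,
                                   tolower(m), d)))
        }
      }
    }
  })

  # -- atypicality --------------------------------------------------------
  say("stage atypicality")
  atyp_table <- timed("atypicality", atypicality_table(records, table))
  write_atypicality(atyp_table, file.path(out, "atypicality.tsv"))

  # -- stats --------------------------------------------------------------
  report_path <- file.path(out, "report.tsv")
  if (resume && file.exists(report_path) &&
      file.exists(file.path(out, "battery.rds"))) {
    battery <- readRDS(file.path(out, "battery.rds"))
  } else {
    say("stage stats")
    battery <- timed("stats", run_full_battery(
      atyp_table, alpha = config$alpha,
      bootstrap_reps = config$bootstrap_reps,
      prediction_resamples = config$prediction_resamples,
      seed = config$seed))
    write_battery_report(battery, report_path)
    saveRDS(battery, file.path(out, "battery.rds"))
  }

  outputs <- list.files(out, pattern = "\\.(tsv|txt)$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(out_dir = out, manifest = manifest,
                 atypicality = atyp_table, battery = battery, cv = cv))
}
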