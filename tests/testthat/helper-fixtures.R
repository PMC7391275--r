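# Programmatic fixtures; nothing is read from disk.

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_normative = 30, n_atypical = 10,
                   grid_shape = c(6, 6, 6), lesion_radius_range = c(1, 2),
                   seed = 42)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

tiny_cohort <- function(...) {
  spec <- tiny_spec(...)
  coh <- generate_cohort(spec)
  list(spec = spec, table = coh$table, truth = coh$truth,
       dataset = generate_scalar_maps(coh$table, coh$truth, spec))
}

# A hand-built dataset with a known linear age/sex plane at every voxel, on
# a minimal grid; useful for GP tests that need full control of the truth.
make_linear_dataset <- function(n = 30, nv = 3, noise = c(0.02, 0.05),
                                fa_slope = 0.01, md_slope = -0.03,
                                seed = 1) {
  set.seed(seed)
  pma <- runif(n, 37, 45)
  sex <- rbinom(n, 1, 0.5)
  fa <- sapply(seq_len(nv), function(v)
    0.3 + fa_slope * (pma - 40) + 0.005 * sex + rnorm(n, 0, noise[1]))
  md <- sapply(seq_len(nv), function(v)
    1.1 + md_slope * (pma - 40) - 0.01 * sex + rnorm(n, 0, noise[2]))
  values <- array(c(fa, md), c(n, nv, 2),
                  dimnames = list(sprintf("sub-%04d", seq_len(n)), NULL,
                                  c("FA", "MD")))
  mask <- array(FALSE, c(4, 4, 4))
  mask[seq_len(nv)] <- TRUE
  table <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                      group = "normative", pma_scan = pma, ga_birth = 39,
                      sex = sex, motion = 1, imd = 20,
                      stringsAsFactors = FALSE)
  list(dataset = voxel_dataset(values, mask), table = table, pma = pma,
       sex = sex)
}

# Deviation-maps object built directly from a Z array (unit-test scaffolding
# for the thresholding/overlap/index operations).
dev_from_z <- function(z, valid = rep(TRUE, dim(z)[2]), threshold = NULL) {
  dimnames(z)[[3]] <- c("FA", "MD")
  ids <- dimnames(z)[[1]] %||% sprintf("sub-%04d", seq_len(dim(z)[1]))
  dimnames(z)[[1]] <- ids
  dev <- structure(list(z = z, valid = valid, subject_ids = ids,
                        include_noise = TRUE, threshold = NULL),
                   class = "deviation_maps")
  if (!is.null(threshold)) dev <- threshold_extremes(dev, threshold)
  dev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
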