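#' Spearman rank correlation test
#'
#' rho is the Pearson correlation of mid-ranks. The two-sided p-value uses
#' the t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom; for n <= 9 an exact permutation p-value (full
#' enumeration of rank permutations) is available via `exact = TRUE`.
#'
#' @param x,y Equal-length numeric vectors without missing values (drop
#'   pairwise before calling).
#' @param exact Use full permutation enumeration for the p-value (n <= 9
#'   only).
#' @param label Optional label carried into the result.
#' @return A list of class `voxnorm_test`: `statistic` (rho), `p_value`,
#'   `effect` (rho), `n`, `method`, `label`.
#' @export
spearman_test <- function(x, y, exact = FALSE, label = NULL) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values: drop pairwise first")
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 9) stop("exact permutation p only available for n <= 9")
    perms <- all_permutations(n)
    # evaluate rho for every permutation of y's ranks
    rho_perm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "Spearman (exact permutation)"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), n - 2)
    }
    method <- "Spearman (t approximation)"
  }
  structure(list(statistic = rho, p_value = p, effect = rho, n = n,
                 method = method, label = label),
            class = "voxnorm_test")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.voxnorm_test <- function(x, ...) {
  cat(x$method, if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat("  statistic =", format(x$statistic), " effect =", format(x$effect),
      " p =", format.pval(x$p_value), " n =", paste(x$n, collapse = "/"),
      "\n")
  invisible(x)
}

#' Mann-Whitney U test with Vargha-Delaney A
#'
#' U is computed from mid-ranks (so ties count one half), and the
#' two-sided p-value uses the normal approximation with tie correction and
#' continuity correction -- appropriate at the cohort sizes this package
#' targets. The probability-of-superiority effect size
#' A = U_x / (n_x n_y) is returned jointly.
#'
#' @param x,y The two groups (x first: A is the probability that a random
#'   x exceeds a random y, ties counted half).
#' @param label Optional label.
#' @return A `voxnorm_test` with `statistic` (U of x), `effect` (A),
#'   `p_value`, `n` (two group sizes).
#' @export
mann_whitney_test <- function(x, y, label = NULL) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 1 || ny < 1) stop("empty group")
  if (anyNA(x) || anyNA(y)) stop("missing values: drop before calling")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  A <- U / (nx * ny)
  N <- nx + ny
  ties <- table(c(x, y))
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1  # all values tied: no evidence of a shift
  } else {
    z <- U - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    p <- min(p, 1)
  }
  structure(list(statistic = U, p_value = p, effect = A, n = c(nx, ny),
                 method = "Mann-Whitney U (normal approximation)",
                 label = label),
            class = "voxnorm_test")
}

#' Vargha-Delaney A effect size
#'
#' A = (#\{x_i > y_j\} + 0.5 #\{x_i = y_j\}) / (n_x n_y): the probability
#' that a randomly drawn x exceeds a randomly drawn y, ties counted half.
#' 0.5 means no effect.
#'
#' @param x,y The two groups.
#' @return A scalar in \[0, 1\].
#' @export
vargha_delaney_A <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  U / (length(x) * length(y))
}

#' Holm (Bonferroni-Holm) step-down correction
#'
#' Sort p-values ascending; adjusted p_(i) = max_{j <= i} min(1,
#' (m - j + 1) p_(j)); reject while adjusted p <= alpha.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error level.
#' @return A list: `adjusted` (same order as input), `reject` (logical).
#' @export
holm_correct <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[ord]))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Ordinary least squares with the reporting used by the battery
#'
#' Fits outcome ~ predictors by OLS and reports per-term two-sided t
#' p-values, R-squared and adjusted R-squared, the overall F test, and two
#' residual diagnostics (Shapiro-Wilk normality and a Breusch-Pagan
#' heteroscedasticity check) -- reported alongside, never gating.
#'
#' @param outcome Numeric response.
#' @param predictors data.frame of numeric predictors.
#' @return A list of class `linear_model_result`.
#' @export
fit_linear_model <- function(outcome, predictors) {
  stopifnot(is.data.frame(predictors), nrow(predictors) == length(outcome))
  n <- length(outcome)
  p <- ncol(predictors)
  if (n <= p + 1) stop("need n > p + 1 observations")
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- data.frame(.outcome = outcome, predictors)
  fit <- lm(.outcome ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_overall <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  shap <- shapiro.test(resid(fit))
  bp <- lmtest::bptest(fit)
  structure(list(
    fit = fit,
    coefficients = sm$coefficients,
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    fstat = c(value = unname(fstat[1]), df1 = unname(fstat[2]),
              df2 = unname(fstat[3])),
    p_overall = unname(p_overall),
    residual_normality = list(test = "Shapiro-Wilk",
                              p = unname(shap$p.value)),
    heteroscedasticity = list(test = "Breusch-Pagan",
                              p = unname(bp$p.value)),
    n = n), class = "linear_model_result")
}

#' @export
print.linear_model_result <- function(x, ...) {
  cat("OLS: adj R^2 =", round(x$adj_r2, 3), " F(", x$fstat["df1"], ",",
      x$fstat["df2"], ") =", round(x$fstat["value"], 2), " p =",
      format.pval(x$p_overall), "\n")
  invisible(x)
}

adj_r2_of <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Case-resampling bootstrap CI for adjusted R-squared
#'
#' Resamples rows with replacement, refits the OLS model, and returns the
#' percentile interval of the adjusted R-squared draws. Singular resamples
#' are redrawn (and counted); more than 10% singular resamples is an
#' error. By default negative draws are kept as observed; `truncate_at_zero`
#' floors the interval at 0.
#'
#' @param outcome,predictors As in [fit_linear_model()].
#' @param reps Bootstrap replications (default 1000).
#' @param level Confidence level.
#' @param seed Seed.
#' @param truncate_at_zero Floor the interval at 0?
#' @return A list: `low`, `high`, `draws`, `level`, `n_redrawn`.
#' @export
bootstrap_ci_adj_r2 <- function(outcome, predictors, reps = 1000,
                                level = 0.95, seed = 1,
                                truncate_at_zero = FALSE) {
  X <- cbind(1, as.matrix(predictors))
  n <- length(outcome)
  p <- ncol(predictors)
  with_seed(seed, {
    draws <- numeric(reps)
    n_redrawn <- 0L
    for (b in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank == ncol(X)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * reps) {
          stop("more than 10% singular bootstrap resamples: ",
               "design too fragile")
        }
      }
      yb <- outcome[idx]
      fit <- lm.fit(Xb, yb)
      r2 <- 1 - sum(fit$residuals^2) / sum((yb - mean(yb))^2)
      draws[b] <- adj_r2_of(r2, n, p)
    }
    ci <- unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
    if (truncate_at_zero) ci <- pmax(ci, 0)
    list(low = ci[1], high = ci[2], draws = draws, level = level,
         n_redrawn = n_redrawn)
  })
}

#' Bootstrap out-of-bag prediction accuracy
#'
#' For each resample, the model is fitted on the bootstrap sample and the
#' adjusted R-squared of its predictions is evaluated on the out-of-bag
#' rows; the mean across resamples estimates prediction accuracy. Empty
#' out-of-bag sets are redrawn (and logged); when an out-of-bag set is too
#' small to support the adjustment (n_oob <= p + 1) the unadjusted
#' R-squared is used for that draw.
#'
#' @inheritParams bootstrap_ci_adj_r2
#' @param resamples Number of bootstrap resamples (default 100).
#' @return A list: `mean` (mean out-of-bag adjusted R-squared), `draws`,
#'   `n_redrawn`.
#' @export
bootstrap_prediction_r2 <- function(outcome, predictors, resamples = 100,
                                    seed = 1) {
  X <- cbind(1, as.matrix(predictors))
  n <- length(outcome)
  p <- ncol(predictors)
  with_seed(seed, {
    draws <- numeric(resamples)
    n_redrawn <- 0L
    for (b in seq_len(resamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        Xb <- X[idx, , drop = FALSE]
        ok <- length(oob) >= 2 && qr(Xb)$rank == ncol(X)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10 * resamples) stop("cannot draw usable resamples")
      }
      fit <- lm.fit(Xb, outcome[idx])
      pred <- X[oob, , drop = FALSE] %*% fit$coefficients
      yo <- outcome[oob]
      r2 <- 1 - sum((yo - pred)^2) / sum((yo - mean(yo))^2)
      draws[b] <- if (length(oob) > p + 1) adj_r2_of(r2, length(oob), p)
                  else r2
    }
    list(mean = mean(draws), draws = draws, n_redrawn = n_redrawn)
  })
}

#' Influential-observation sensitivity rerun
#'
#' Standardizes the atypicality index across subjects (sample SD, n - 1),
#' removes observations with |Z| > `threshold`, and recomputes the Spearman
#' test against the paired outcome. Both the full and trimmed results are
#' returned together with the dropped subjects.
#'
#' @param index Numeric atypicality index values.
#' @param outcome Paired outcome values.
#' @param ids Optional subject ids (for reporting the dropped ones).
#' @param threshold Z threshold for removal (default 3.1).
#' @return A list: `full`, `trimmed` (both `voxnorm_test`), `dropped`.
#' @export
sensitivity_rerun <- function(index, outcome, ids = NULL, threshold = 3.1) {
  n <- length(index)
  if (n < 5) stop("at least 5 subjects are required")
  ids <- ids %||% as.character(seq_len(n))
  z <- (index - mean(index)) / sd(index)
  drop <- abs(z) > threshold
  if (all(drop)) stop("all observations dropped")
  full <- spearman_test(index, outcome, label = "full")
  trimmed <- spearman_test(index[!drop], outcome[!drop], label = "trimmed")
  list(full = full, trimmed = trimmed, dropped = ids[drop])
}

battery_indices <- c("fa_plus", "fa_minus", "md_plus", "md_minus")

#' Run the full statistical battery
#'
#' Mirrors the two-stage analysis flow: (1) four group comparisons of the
#' atypicality indices (Mann-Whitney U with Vargha-Delaney A), (2) Spearman
#' correlations of each index with GA at birth within each group, (3)
#' Spearman correlations of each index with each outcome within each
#' group, with Holm correction applied within each family separately; then
#' (4) for every index-outcome pair significant after correction in the
#' atypical group, a multiple linear regression of the outcome on the
#' index plus GA at birth, sex, head motion and deprivation score, with a
#' bootstrap CI for the adjusted R-squared, bootstrap out-of-bag
#' prediction accuracy, and an influential-observation sensitivity rerun
#' of the correlation.
#'
#' @param table A joined atypicality table from [atypicality_table()].
#' @param alpha Family-wise error level.
#' @param bootstrap_reps Replications for the adjusted R-squared CI.
#' @param prediction_resamples Resamples for prediction accuracy.
#' @param seed Seed for all bootstrap stages.
#' @param outcomes Outcome column names to test.
#' @return A list of class `battery_report`: `report` (one row per test:
#'   family, group, index, outcome, statistic, effect, n, p, p_adj,
#'   significant), `models` (per significant atypical index-outcome pair:
#'   regression, bootstrap CI, prediction accuracy, sensitivity rerun),
#'   `alpha`, `seed`.
#' @export
run_full_battery <- function(table, alpha = 0.05, bootstrap_reps = 1000,
                             prediction_resamples = 100, seed = 1,
                             outcomes = c("outcome_cognitive",
                                          "outcome_language",
                                          "outcome_motor")) {
  stopifnot(all(battery_indices %in% names(table)),
            all(c("group", "ga_birth") %in% names(table)))
  outcomes <- outcomes[outcomes %in% names(table)]
  missing_out <- setdiff(c("outcome_cognitive", "outcome_language",
                           "outcome_motor"), names(table))
  if (length(missing_out)) {
    warning("outcome column(s) missing, tests skipped: ",
            paste(missing_out, collapse = ", "))
  }
  atyp <- table[table$group == "atypical", , drop = FALSE]
  norm <- table[table$group == "normative", , drop = FALSE]

  rows <- list()
  # degenerate inputs (e.g. an index that is constant within a group) yield
  # an NA row rather than aborting the battery; NA rows take no part in the
  # Holm correction and are never significant
  add_row <- function(family, group, index, outcome, test) {
    if (inherits(test, "try-error")) {
      test <- list(statistic = NA_real_, effect = NA_real_, n = NA,
                   p_value = NA_real_)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      family = family, group = group, index = index,
      outcome = outcome %||% NA_character_,
      statistic = test$statistic, effect = test$effect,
      n = paste(test$n, collapse = "/"), p = test$p_value,
      stringsAsFactors = FALSE)
  }

  # family 1: group comparisons (atypical vs normative)
  if (nrow(atyp) > 1 && nrow(norm) > 1) {
    for (ix in battery_indices) {
      add_row("group_comparison", "atypical_vs_normative", ix, NULL,
              mann_whitney_test(atyp[[ix]], norm[[ix]]))
    }
  }
  # families 2: GA correlations within each group
  for (g in c("normative", "atypical")) {
    sub <- table[table$group == g, , drop = FALSE]
    if (nrow(sub) < 3) next
    for (ix in battery_indices) {
      add_row("ga_correlation", g, ix, NULL,
              try(spearman_test(sub$ga_birth, sub[[ix]]), silent = TRUE))
    }
  }
  # families 3: outcome correlations within each group
  for (g in c("normative", "atypical")) {
    sub <- table[table$group == g, , drop = FALSE]
    for (oc in outcomes) {
      keep <- !is.na(sub[[oc]])
      if (sum(keep) < 3) next
      for (ix in battery_indices) {
        add_row("outcome_correlation", g, ix, oc,
                try(spearman_test(sub[[ix]][keep], sub[[oc]][keep]),
                    silent = TRUE))
      }
    }
  }
  report <- do.call(rbind, rows)
  report$p_adj <- NA_real_
  report$significant <- FALSE
  for (fam in unique(paste(report$family, report$group))) {
    sel <- paste(report$family, report$group) == fam & !is.na(report$p)
    if (!any(sel)) next
    h <- holm_correct(report$p[sel], alpha)
    report$p_adj[sel] <- h$adjusted
    report$significant[sel] <- h$reject
  }

  # stage 2: regressions for significant atypical index-outcome pairs
  models <- list()
  sig <- report$family == "outcome_correlation" &
    report$group == "atypical" & report$significant
  covars <- c("ga_birth", "sex", "motion", "imd")
  for (i in which(sig)) {
    ix <- report$index[i]
    oc <- report$outcome[i]
    sub <- atyp[stats::complete.cases(atyp[, c(oc, ix, covars)]), ,
                drop = FALSE]
    if (nrow(sub) <= length(covars) + 2) next
    preds <- sub[, c(ix, covars)]
    key <- paste(ix, oc, sep = ":")
    # a too-fragile design (e.g. very few subjects) fails this model's
    # bootstrap loudly but must not abort the rest of the battery
    models[[key]] <- tryCatch(list(
      regression = fit_linear_model(sub[[oc]], preds),
      ci_adj_r2 = bootstrap_ci_adj_r2(sub[[oc]], preds,
                                      reps = bootstrap_reps, seed = seed),
      prediction_r2 = bootstrap_prediction_r2(
        sub[[oc]], preds, resamples = prediction_resamples, seed = seed),
      sensitivity = sensitivity_rerun(sub[[ix]], sub[[oc]],
                                      ids = sub$subject_id)),
      error = function(e) {
        warning("regression stage skipped for ", key, ": ",
                conditionMessage(e), call. = FALSE)
        list(error = conditionMessage(e))
      })
  }
  structure(list(report = report, models = models, alpha = alpha,
                 seed = seed), class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat("battery_report:", nrow(x$report), "tests,",
      sum(x$report$significant), "significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Write a battery report as TSV
#'
#' @param battery A `battery_report`.
#' @param path TSV path for the test table; a sibling `*_models.txt`
#'   summarises the regressions.
#' @return Invisibly, `path`.
#' @export
write_battery_report <- function(battery, path) {
  tab <- battery$report
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.15g", v))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- sub("\\.tsv$", "_models.txt", path)
  con <- file(mp, "w")
  on.exit(close(con))
  for (key in names(battery$models)) {
    m <- battery$models[[key]]
    if (!is.null(m$error)) {
      writeLines(sprintf("%s: skipped (%s)", key, m$error), con)
      next
    }
    writeLines(sprintf(
      "%s: adj_R2=%.6g F(%g,%g)=%.6g p=%.6g CI[%.6g, %.6g] pred_R2=%.6g dropped=%s",
      key, m$regression$adj_r2, m$regression$fstat["df1"],
      m$regression$fstat["df2"], m$regression$fstat["value"],
      m$regression$p_overall, m$ci_adj_r2$low, m$ci_adj_r2$high,
      m$prediction_r2$mean,
      paste(m$sensitivity$dropped, collapse = ",")), con)
  }
  invisible(path)
}
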