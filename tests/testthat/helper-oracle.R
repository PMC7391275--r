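# Independent dense-linear-algebra oracles, deliberately written with plain
# base R (solve/determinant on full matrices) and kept free of any code path
# from the package's compiled core.

oracle_build_K <- function(theta, x, jitter = 1e-8) {
  ell <- exp(theta[1])
  L <- matrix(c(exp(theta[2]), theta[3], 0, exp(theta[4])), 2, 2)
  B <- L %*% t(L)
  s <- exp(theta[5:6])
  D2 <- as.matrix(dist(x))^2
  E <- exp(-0.5 * D2 / ell^2)
  n <- nrow(x)
  K <- rbind(cbind(B[1, 1] * E, B[1, 2] * E),
             cbind(B[2, 1] * E, B[2, 2] * E))
  diag(K)[1:n] <- diag(K)[1:n] + s[1]
  diag(K)[(n + 1):(2 * n)] <- diag(K)[(n + 1):(2 * n)] + s[2]
  diag(K) <- diag(K) + jitter
  list(K = K, B = B, s = s, ell = ell)
}

oracle_lml <- function(theta, x, y, jitter = 1e-8) {
  kk <- oracle_build_K(theta, x, jitter)
  m <- length(y)
  -0.5 * drop(t(y) %*% solve(kk$K, y)) -
    0.5 * as.numeric(determinant(kk$K, logarithm = TRUE)$modulus) -
    0.5 * m * log(2 * pi)
}

oracle_posterior <- function(theta, x, xq, y, include_noise = TRUE,
                             jitter = 1e-8) {
  kk <- oracle_build_K(theta, x, jitter)
  n <- nrow(x)
  q <- nrow(xq)
  Kinv <- solve(kk$K)
  d2c <- outer(rowSums(x^2), rep(1, q)) + outer(rep(1, n), rowSums(xq^2)) -
    2 * x %*% t(xq)
  Ec <- exp(-0.5 * d2c / kk$ell^2)
  mean_out <- matrix(0, q, 2)
  var_out <- matrix(0, q, 2)
  for (b in 1:2) {
    Kstar <- rbind(kk$B[1, b] * Ec, kk$B[2, b] * Ec)
    mean_out[, b] <- t(Kstar) %*% Kinv %*% y
    var_out[, b] <- kk$B[b, b] - diag(t(Kstar) %*% Kinv %*% Kstar)
    if (include_noise) var_out[, b] <- var_out[, b] + kk$s[b]
  }
  list(mean = mean_out, sd = sqrt(var_out))
}

# Exact Mann-Whitney permutation p: enumerate every assignment of the pooled
# values into groups of size nx/ny and compare the A effect size's distance
# from 1/2.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  a_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    (sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))) /
      (length(xs) * length(ys))
  }
  a_obs <- a_of(seq_len(nx))
  combos <- utils::combn(length(pooled), nx)
  stat <- apply(combos, 2, function(idx) abs(a_of(idx) - 0.5))
  mean(stat >= abs(a_obs - 0.5) - 1e-12)
}

ols_slope_se <- function(y, X) {
  fit <- lm(y ~ X)
  list(coef = coef(fit), se = sqrt(diag(vcov(fit))))
}
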