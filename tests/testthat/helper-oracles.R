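# Brute-force oracles and tiny fixture builders shared across test files.
# Oracles deliberately use dense linear algebra and closed forms, independent
# of the package's assembly paths.

# dense marginal covariance of one time-point: V = sum_b Z_b G_b Z_b' + s2 I,
# with Z_b expanded per level of its grouping factor
dense_V <- function(blocks, G_list, sigma2, N) {
  V <- diag(sigma2, N)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (lv in levels(droplevels(b$group))) {
      r <- which(b$group == lv)
      Zg <- b$Z[r, , drop = FALSE]
      V[r, r] <- V[r, r] + Zg %*% G_list[[bi]] %*% t(Zg)
    }
  }
  V
}

# GLS estimate and covariance by explicit dense inversion
gls_oracle <- function(X, V, y) {
  Vinv <- solve(V)
  A <- solve(t(X) %*% Vinv %*% X)
  list(beta = drop(A %*% t(X) %*% Vinv %*% y), vcov = A,
       M = A %*% t(X) %*% Vinv)
}

# full-joint covariance oracle: builds the NS x NS covariance of all
# observations across time-points and propagates it through the exact
# per-time-point linear estimator maps M(s) (p x N each)
joint_cov_oracle <- function(M_by_s, Sigma_pairs) {
  S <- length(M_by_s)
  p <- nrow(M_by_s[[1]])
  out <- lapply(seq_len(p), function(k) matrix(NA_real_, S, S))
  for (s1 in seq_len(S)) {
    for (s2 in seq_len(S)) {
      C <- M_by_s[[s1]] %*% Sigma_pairs[[s1]][[s2]] %*% t(M_by_s[[s2]])
      for (k in seq_len(p)) out[[k]][s1, s2] <- C[k, k]
    }
  }
  out
}

# textbook paired t-test from subject-level differences
paired_t_oracle <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1),
       lo = m - qt(0.975, n - 1) * s / sqrt(n),
       hi = m + qt(0.975, n - 1) * s / sqrt(n))
}

# direct-summation trapezoid, written element by element
trapz_oracle <- function(t, y) {
  acc <- 0
  for (i in seq_len(length(t) - 1)) {
    acc <- acc + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  acc
}

# tiny functional dataset with iid noise and a binary covariate
make_toy_fd <- function(n_subj = 2, trials_per_cond = 3, S = 2, seed = 1,
                        noise_sd = 1, beta = NULL, re_sd = 0) {
  set.seed(seed)
  J <- 2 * trials_per_cond
  id <- rep(sprintf("s%02d", seq_len(n_subj)), each = J)
  x <- rep(rep(c(0, 1), each = trials_per_cond), n_subj)
  if (is.null(beta)) beta <- rbind(rep(1, S), rep(0.5, S))
  Y <- cbind(1, x) %*% beta + matrix(rnorm(n_subj * J * S, sd = noise_sd),
                                     n_subj * J, S)
  if (re_sd > 0) {
    u <- rnorm(n_subj, sd = re_sd)
    Y <- Y + u[rep(seq_len(n_subj), each = J)]
  }
  df <- data.frame(id = id, x = x)
  df[paste0("y_", seq_len(S))] <- as.data.frame(Y)
  fd_data(df, signal_cols = paste0("y_", seq_len(S)),
          time_grid = (seq_len(S) - 1) / 15)
}
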