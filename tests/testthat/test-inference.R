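# dense Sigma(s1, s2) = sum_b sum_g Z_g G_b(s1,s2) Z_g' + r(s1,s2) I
dense_sigma_pair <- function(blocks, G_pair, r_resid, N) {
  Sig <- diag(r_resid, N)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (lv in levels(droplevels(b$group))) {
      r <- which(b$group == lv)
      Zg <- b$Z[r, , drop = FALSE]
      Sig[r, r] <- Sig[r, r] + Zg %*% G_pair[[bi]] %*% t(Zg)
    }
  }
  Sig
}

# brute-force covariance of the smoothed coefficients from known components;
# R_resid is the S x S trial-level residual cross-covariance (sigma2 on the
# diagonal, zero off-diagonal when absent)
brute_cov <- function(fit, H_list, G_cross, sigma2) {
  S <- dim(G_cross$G[[1]])[3]
  X <- fit$design$X
  N <- nrow(X)
  p <- ncol(X)
  R_resid <- G_cross$R
  if (is.null(R_resid)) {
    R_resid <- diag(sigma2, S)
  }
  M_by_s <- lapply(seq_len(S), function(s) {
    Gs <- lapply(G_cross$G, function(a) matrix(a[, , s, s], sqrt(length(a[, , s, s]))))
    V <- dense_sigma_pair(fit$design$blocks, Gs, sigma2[s], N)
    gls_oracle(X, V, rep(0, N))$M
  })
  Sigma_pairs <- lapply(seq_len(S), function(s1) {
    lapply(seq_len(S), function(s2) {
      Gp <- lapply(G_cross$G, function(a) matrix(a[, , s1, s2], sqrt(length(a[, , s1, s2]))))
      dense_sigma_pair(fit$design$blocks, Gp, R_resid[s1, s2], N)
    })
  })
  raw <- joint_cov_oracle(M_by_s, Sigma_pairs)
  lapply(seq_len(p), function(k) H_list[[k]] %*% raw[[k]] %*% t(H_list[[k]]))
}

test_that("assembled covariance matches the dense full-joint oracle with known components", {
  fd <- make_toy_fd(n_subj = 2, trials_per_cond = 3, S = 2, seed = 4,
                    noise_sd = 0.8, re_sd = 0.6)
  fit <- fit_pointwise(fd, "y ~ x + (x | id)")
  S <- 2
  G <- array(NA_real_, c(2, 2, S, S))
  G[, , 1, 1] <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  G[, , 2, 2] <- matrix(c(0.4, 0.05, 0.05, 0.2), 2)
  G12 <- matrix(c(0.3, 0.02, 0.05, 0.15), 2)
  G[, , 1, 2] <- G12
  G[, , 2, 1] <- t(G12)
  G_known <- list(G = list(G), idx = 1:2)
  sigma2 <- c(1.0, 1.3)
  fit$sigma2 <- sigma2
  # diagonal Wald pieces recomputed densely from the known components
  for (s in 1:S) {
    V <- dense_sigma_pair(fit$design$blocks, list(G[, , s, s]), sigma2[s],
                          nrow(fit$design$X))
    fit$vcov[, , s] <- gls_oracle(fit$design$X, V, rep(0, nrow(V)))$vcov
  }
  sm <- smooth_coefficients(fit)  # S = 2: identity smoother
  got <- covariance_beta(fit, sm, G_cross = G_known)
  want <- brute_cov(fit, sm$H, G_known, sigma2)
  for (k in 1:2) expect_equal(got[[k]], want[[k]], tolerance = 1e-8)
})

test_that("fast assembly matches the dense oracle on a nested design with a real smoother", {
  set.seed(6)
  S <- 5
  n_subj <- 2
  df <- expand.grid(trial = 1:4, session_k = 1:2, id = c("a", "b"),
                    stringsAsFactors = FALSE)
  df$session <- paste0(df$id, "_s", df$session_k)
  df$x <- rnorm(nrow(df))
  Y <- matrix(rnorm(nrow(df) * S), nrow(df), S) + 0.5 * df$x
  df[paste0("y_", 1:S)] <- as.data.frame(Y)
  fd <- fd_data(df, paste0("y_", 1:S), subject = "id", session = "session")
  fit <- fit_pointwise(fd, "y ~ x + (1 | id/session)")
  G_cross <- estimate_G_cross(fit)
  ctl <- flmm_control(basis_size = 4)
  sm <- smooth_coefficients(fit, ctl)
  got <- covariance_beta(fit, sm, G_cross = G_cross)
  # overwrite diagonal Wald pieces densely so both routes share components
  for (s in 1:S) {
    Gs <- lapply(G_cross$G, function(a) matrix(a[, , s, s], 1))
    V <- dense_sigma_pair(fit$design$blocks, Gs, fit$sigma2[s],
                          nrow(fit$design$X))
    fit$vcov[, , s] <- gls_oracle(fit$design$X, V, rep(0, nrow(V)))$vcov
  }
  got2 <- covariance_beta(fit, sm, G_cross = G_cross)
  want <- brute_cov(fit, sm$H, G_cross, fit$sigma2)
  for (k in 1:2) {
    expect_equal(got2[[k]], want[[k]], tolerance = 1e-8)
    # lme4's Wald vcov agrees with the dense route, so the public path does too
    expect_equal(got[[k]], want[[k]], tolerance = 1e-5)
  }
})

test_that("a single time-point reduces to the scalar mixed model", {
  fd <- make_toy_fd(n_subj = 6, trials_per_cond = 5, S = 1, seed = 10,
                    re_sd = 0.7)
  fit <- fit_flmm(fd, "y ~ x + (1 | id)")
  ref <- lme4::lmer(y ~ x + (1 | id),
                    data = data.frame(y = drop(signal_matrix(fd)), x = fd$x,
                                      id = fd_subject(fd)))
  expect_equal(unname(fit$beta_tilde[, 1]), unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se_pointwise[, 1]),
               unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  expect_equal(fit$bic, BIC(ref), tolerance = 1e-6)
  # with one time-point the joint band is the pointwise band up to
  # Monte-Carlo error in the critical-value quantile (floored at z)
  expect_true(all(fit$q_crit >= qnorm(0.975)))
  expect_equal(unname(fit$q_crit), rep(qnorm(0.975), 2), tolerance = 0.05)
})

test_that("joint critical values hit their closed-form limits", {
  q1 <- joint_critical_value(diag(1), draws = 1e5, seed = 2)
  expect_equal(q1, qnorm(0.975), tolerance = 0.02)

  q2_indep <- joint_critical_value(diag(2), draws = 1e5, seed = 2)
  # root of (2 Phi(q) - 1)^2 = 0.95 for the max of two independent |N(0,1)|
  q_closed <- qnorm((1 + sqrt(0.95)) / 2)
  expect_equal(q_closed, 2.2365, tolerance = 1e-4)
  expect_equal(q2_indep, q_closed, tolerance = 0.02)

  q2_perfect <- joint_critical_value(matrix(1, 2, 2), draws = 1e5, seed = 2)
  expect_equal(q2_perfect, qnorm(0.975), tolerance = 0.02)
})

test_that("the critical value decreases as correlation increases", {
  S <- 40
  cs <- function(rho) {
    m <- matrix(rho, S, S)
    diag(m) <- 1
    m
  }
  q_indep <- joint_critical_value(diag(S), draws = 2e4, seed = 3)
  q_half <- joint_critical_value(cs(0.5), draws = 2e4, seed = 3)
  q_one <- joint_critical_value(cs(1), draws = 2e4, seed = 3)
  expect_gt(q_indep, q_half - 0.02)
  expect_gt(q_half, q_one - 0.02)
  expect_equal(q_one, qnorm(0.975), tolerance = 0.02)
  expect_lt(joint_critical_value(diag(1), draws = 5e4, seed = 1) - qnorm(0.975),
            0.02)
})

test_that("few draws trigger a quantile-instability warning", {
  expect_warning(joint_critical_value(diag(2), draws = 500, seed = 1),
                 "1000")
})

test_that("the joint band always contains the pointwise band", {
  cfg <- sim_config(n_subjects = 5, trials_per_condition = 8, S = 20, seed = 12)
  sim <- simulate_dataset(cfg)
  fit <- fit_flmm(sim$data, "y ~ x + (x | id)")
  expect_true(all(fit$q_crit >= qnorm(0.975)))
  td <- tidy(fit)
  expect_true(all(td$joint_lo <= td$pointwise_lo + 1e-12))
  expect_true(all(td$joint_hi >= td$pointwise_hi - 1e-12))
  expect_true(all(td$se >= 0))
  for (k in seq_along(fit$cov_beta)) {
    C <- fit$cov_beta[[k]]
    expect_equal(C, t(C), tolerance = 1e-10)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(diag(C)))
  }
})

test_that("identical data and seed give identical bands after shuffling trials", {
  cfg <- sim_config(n_subjects = 4, trials_per_condition = 6, S = 12, seed = 30)
  sim <- simulate_dataset(cfg)
  set.seed(77)
  perm <- sample(nrow(sim$data))
  fd2 <- fd_data(as.data.frame(sim$data)[perm, ],
                 attr(sim$data, "signal_cols"), time_grid(sim$data))
  # fixed smoothing isolates order-independence of the estimation pipeline;
  # data-driven lambda selection is deterministic in its input but can flip
  # one grid step when summation order perturbs estimates at optimizer
  # tolerance
  ctl <- flmm_control(selector = "fixed", lambda_fixed = 1)
  f1 <- fit_flmm(sim$data, "y ~ x + (x | id)", control = ctl)
  f2 <- fit_flmm(fd2, "y ~ x + (x | id)", control = ctl)
  # agreement is limited only by the optimizer's convergence tolerance,
  # since summation order changes with row order
  expect_equal(f1$beta_tilde, f2$beta_tilde, tolerance = 1e-4)
  expect_equal(f1$se_pointwise, f2$se_pointwise, tolerance = 5e-3)
  expect_equal(f1$q_crit, f2$q_crit, tolerance = 1e-2)
  # identical input gives bitwise-identical selection and bands
  f3 <- fit_flmm(sim$data, "y ~ x + (x | id)")
  f4 <- fit_flmm(sim$data, "y ~ x + (x | id)")
  expect_identical(f3$se_joint_halfwidth, f4$se_joint_halfwidth)
})

test_that("non-gaussian families point to the unimplemented bootstrap path", {
  fd <- make_toy_fd(S = 4, seed = 1)
  expect_error(fit_flmm(fd, "y ~ x + (1 | id)",
                        flmm_control(family = "poisson")),
               "not implemented|gaussian")
})

test_that("stage errors are labeled with their stage", {
  fd <- make_toy_fd(S = 4, seed = 1)
  expect_error(fit_flmm(fd, "y ~ x + (x || id)"), "\\[stage formula\\]")
  expect_error(fit_flmm(fd, "y ~ nope + (1 | id)"), "\\[stage pointwise\\]")
})
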