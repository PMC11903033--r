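test_that("with zero kernels and no noise the signal is exactly the mean model", {
  S <- 12
  tr <- default_truth(S)
  zero <- matrix(0, S, S)
  cfg <- sim_config(n_subjects = 3, trials_per_condition = 4, S = S,
                    beta0 = tr$beta0, beta1 = tr$beta1,
                    K_gamma0 = zero, K_gamma1 = zero, K_eps = zero,
                    eps_scale = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  Y <- signal_matrix(sim$data)
  want <- matrix(tr$beta0, nrow(Y), S, byrow = TRUE) + sim$data$x %o% tr$beta1
  expect_equal(Y, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("sampled random-intercept curves reproduce their kernel at large n", {
  S <- 10
  cfg <- sim_config(n_subjects = 10000, trials_per_condition = 1, S = S,
                    beta0 = rep(0, S), beta1 = rep(0, S),
                    K_gamma0 = se_kernel((0:(S - 1)) / 15, 0.25, 0.5),
                    K_gamma1 = diag(0, S), K_eps = diag(0, S),
                    eps_scale = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  emp <- cov(sim$truth$gamma0)
  K <- cfg$K_gamma0
  # elementwise agreement within 2% of the kernel amplitude on average,
  # and no entry off by more than a few Monte-Carlo standard errors
  rel_err <- abs(emp - K) / max(K)
  expect_lt(mean(rel_err), 0.02)
  expect_lt(max(rel_err), 0.06)
})

test_that("the binary covariate is balanced within every subject", {
  cfg <- sim_config(n_subjects = 5, trials_per_condition = 7, S = 12, seed = 3)
  sim <- simulate_dataset(cfg)
  counts <- table(fd_subject(sim$data), sim$data$x)
  expect_true(all(counts == 7))
})

test_that("default truth has the stated shape and stationary kernels", {
  for (S in c(12, 40, 80)) {
    tr <- default_truth(S)
    first_quarter <- seq_len(floor(S / 4))
    expect_true(all(tr$beta1[first_quarter] == 0))
    expect_true(any(tr$beta1 < 0))
    expect_true(all(tr$beta1 <= 0))
    # the dip reaches -0.5 up to grid discretization of the window
    expect_lt(min(tr$beta1), -0.45)
    expect_gte(min(tr$beta1), -0.5)
    # intercept: fast rise to a positive peak, then slow decay
    peak <- which.max(tr$beta0)
    expect_lt(peak, S / 3)
    expect_gt(tr$beta0[peak], 1)
    for (K in list(tr$K_gamma0, tr$K_gamma1, tr$K_eps)) {
      lag1 <- K[cbind(1:(S - 1), 2:S)]
      expect_lt(diff(range(lag1)), 1e-12)  # depends only on |s1 - s2|
      expect_lt(diff(range(diag(K))), 1e-12)
    }
  }
})

test_that("integrated random-effect to noise variance ratio is in the design band", {
  tr <- default_truth(40)
  ratio <- (sum(diag(tr$K_gamma0)) + 0.5 * sum(diag(tr$K_gamma1))) /
    (5 * sum(diag(tr$K_eps)))
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 0.4)
})

test_that("marginal variance decomposes as the sum of its components", {
  S <- 8
  t8 <- (0:(S - 1)) / 15
  cfg <- sim_config(n_subjects = 3000, trials_per_condition = 1, S = S,
                    beta0 = rep(0, S), beta1 = rep(1, S),
                    K_gamma0 = se_kernel(t8, 0.3, 0.5),
                    K_gamma1 = se_kernel(t8, 0.1, 0.5),
                    K_eps = ou_kernel(t8, 0.2, 0.3),
                    eps_scale = 5, noise_jitter_sd = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  Y <- signal_matrix(sim$data)
  v1 <- apply(Y[sim$data$x == 1, ], 2, var)
  v0 <- apply(Y[sim$data$x == 0, ], 2, var)
  want1 <- diag(cfg$K_gamma0) + diag(cfg$K_gamma1) + 5 * diag(cfg$K_eps)
  want0 <- diag(cfg$K_gamma0) + 5 * diag(cfg$K_eps)
  expect_equal(v1, want1, tolerance = 0.08, ignore_attr = TRUE)
  expect_equal(v0, want0, tolerance = 0.08, ignore_attr = TRUE)
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(n_subjects = 3, trials_per_condition = 4, S = 10, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(signal_matrix(s1$data), signal_matrix(s2$data))
  s3 <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(signal_matrix(s1$data), signal_matrix(s3$data)))
})

test_that("a non-PSD kernel is rejected before sampling", {
  S <- 10
  bad <- diag(S)
  bad[1, S] <- bad[S, 1] <- 2  # indefinite
  cfg <- sim_config(n_subjects = 2, trials_per_condition = 2, S = S,
                    beta0 = rep(0, S), beta1 = rep(0, S),
                    K_gamma0 = bad, K_gamma1 = diag(0, S),
                    K_eps = diag(S), seed = 1)
  expect_error(simulate_dataset(cfg), "positive semidefinite")
})

test_that("error-scale recycling draws at most 7 distinct subject scales", {
  cfg <- sim_config(n_subjects = 12, trials_per_condition = 2, S = 10,
                    share_error_kernel_groups = TRUE, seed = 4)
  sim <- simulate_dataset(cfg)
  expect_lte(length(unique(sim$truth$noise_scales)), 7)
  expect_equal(length(sim$truth$noise_scales), 12)
})

test_that("the nested reward design has the stated interval and session structure", {
  gen <- simulate_iri_design(n_subjects = 4, sessions = 5,
                             trials_per_session = 100, seed = 2, S = 10)
  d <- gen$data
  expect_equal(nrow(d), 4 * 5 * 100)
  counts <- table(fd_session(d))
  expect_true(all(counts == 100))
  # each session belongs to exactly one subject by construction
  expect_equal(length(unique(paste(fd_subject(d), fd_session(d)))),
               4 * 5)

  big <- simulate_iri_design(n_subjects = 5, sessions = 4,
                             trials_per_session = 5000, seed = 3, S = 4)
  expect_equal(mean(big$data$iri), 14, tolerance = 0.02 * 14)
})

test_that("continuous-covariate mode draws a standard normal covariate", {
  cfg <- sim_config(n_subjects = 200, trials_per_condition = 10, S = 10,
                    covariate_type = "continuous", seed = 6)
  sim <- simulate_dataset(cfg)
  expect_equal(mean(sim$data$x), 0, tolerance = 0.05)
  expect_equal(sd(sim$data$x), 1, tolerance = 0.05)
})

test_that("nested reward-design formulas run end-to-end and hold their size", {
  R <- 20
  rejections <- 0
  for (r in seq_len(R)) {
    gen <- simulate_iri_design(n_subjects = 5, sessions = 2,
                               trials_per_session = 25, seed = 300 + r,
                               S = 20)
    fit <- fit_flmm(gen$data, "y ~ iri + (lick_latency | id/session)",
                    control = flmm_control(smooth_blups = FALSE))
    expect_true(all(fit$q_crit >= qnorm(0.975)))
    td <- tidy(fit)
    eff <- td[td$term == "iri", ]
    if (any(eff$joint_lo > 0 | eff$joint_hi < 0)) rejections <- rejections + 1
  }
  # the interval covariate has no effect; a joint-band rejection anywhere on
  # the curve should be a roughly-5% event per replicate
  expect_lte(rejections, 4)
})
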