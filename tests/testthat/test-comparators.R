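make_fd_from_matrix <- function(Y, id, x, rate_hz = 15) {
  df <- data.frame(id = id, x = x)
  df[paste0("y_", seq_len(ncol(Y)))] <- as.data.frame(Y)
  fd_data(df, paste0("y_", seq_len(ncol(Y))),
          time_grid = (seq_len(ncol(Y)) - 1) / rate_hz)
}

test_that("auc summaries agree with hand values and a direct-summation oracle", {
  S <- 16
  time <- (seq_len(S) - 1) / 15
  Y <- rbind(rep(3, S), rep(-1, S))
  fd <- make_fd_from_matrix(Y, c("a", "b"), c(0, 1))
  # constant signal, mean mode -> the constant
  expect_equal(compute_auc(fd, auc_spec(c(0, 0.5))), c(3, -1))

  # window [2,2], baseline [0,0], mean mode -> 2
  Y2 <- matrix(0, 1, S)
  Y2[1, 9:16] <- 2
  fd2 <- make_fd_from_matrix(Y2, "a", 0)
  got <- compute_auc(fd2, auc_spec(c(time[9], time[16]),
                                   baseline_window = c(time[1], time[8])))
  expect_equal(got, 2)

  # trapezoidal integral vs an independent direct summation
  set.seed(14)
  Y3 <- matrix(rnorm(S), 1, S)
  fd3 <- make_fd_from_matrix(Y3, "a", 0)
  idx <- 3:12
  got <- compute_auc(fd3, auc_spec(c(time[3], time[12]), mode = "integral"))
  expect_equal(got, trapz_oracle(time[idx], Y3[1, idx]), tolerance = 1e-12)

  expect_error(compute_auc(fd, auc_spec(c(0, 99))), "outside")
})

test_that("mean-mode auc is invariant to refining a piecewise-constant signal", {
  S1 <- 10
  S2 <- 20
  fd_coarse <- make_fd_from_matrix(matrix(2.5, 1, S1), "a", 0, rate_hz = 15)
  fd_fine <- make_fd_from_matrix(matrix(2.5, 1, S2), "a", 0, rate_hz = 30)
  w <- c(0.1, 0.5)
  expect_equal(compute_auc(fd_coarse, auc_spec(w)),
               compute_auc(fd_fine, auc_spec(w)))
})

test_that("paired t-test matches the textbook formula on a 4-subject example", {
  S <- 4
  ids <- rep(c("a", "b", "c", "d"), each = 2)
  x <- rep(c(0, 1), 4)
  base <- c(1.0, 1.9, 2.0, 2.4, 0.5, 1.6, 3.0, 3.2)
  Y <- matrix(base, 8, S)
  fd <- make_fd_from_matrix(Y, ids, x)
  got <- paired_ttest_auc(fd, auc_spec(c(0, 0.2)), "x")
  d <- c(0.9, 0.4, 1.1, 0.2)
  want <- paired_t_oracle(d)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, 3)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_equal(got$conf_lo, want$lo, tolerance = 1e-10)
  expect_equal(got$conf_hi, want$hi, tolerance = 1e-10)
})

test_that("degenerate equal differences are rejected with a clear error", {
  Y <- matrix(c(0, 1, 2, 3), 4, 2)
  fd <- make_fd_from_matrix(Y, c("a", "a", "b", "b"), c(0, 1, 0, 1))
  expect_error(paired_ttest_auc(fd, auc_spec(c(0, 0.05)), "x"),
               "zero pooled SD")
})

test_that("a subject missing a condition is listed by name", {
  Y <- matrix(rnorm(6), 6, 2)
  fd <- make_fd_from_matrix(Y, c("a", "a", "b", "b", "c", "c"),
                            c(0, 1, 0, 1, 0, 0))
  expect_error(paired_ttest_auc(fd, auc_spec(c(0, 0.05)), "x"),
               "missing a condition: c")
})

test_that("paired t-test holds its size on null data", {
  set.seed(50)
  rejections <- 0
  R <- 500
  for (r in seq_len(R)) {
    Y <- matrix(rnorm(12 * 3), 12, 3)
    fd <- make_fd_from_matrix(Y, rep(c("a", "b", "c", "d", "e", "f"), each = 2),
                              rep(c(0, 1), 6))
    p <- paired_ttest_auc(fd, auc_spec(c(0, 0.1)), "x")$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / R, 0.02)
  expect_lt(rejections / R, 0.08)
})

test_that("auc mixed model degenerates to OLS under zero random-effect variance", {
  fd <- make_toy_fd(n_subj = 4, trials_per_cond = 8, S = 3, seed = 23,
                    noise_sd = 1, re_sd = 0)
  out <- lmm_auc(fd, auc_spec(c(0, 0.1)), "auc ~ x + (1 | id)")
  auc <- compute_auc(fd, auc_spec(c(0, 0.1)))
  ols <- lm(auc ~ fd$x)
  expect_equal(out$estimate, unname(coef(ols)), tolerance = 1e-5)
})

test_that("an S=1 functional fit and the auc mixed model give identical numbers", {
  fd <- make_toy_fd(n_subj = 5, trials_per_cond = 6, S = 1, seed = 29,
                    re_sd = 0.6)
  flmm <- fit_flmm(fd, "y ~ x + (x | id)")
  auc <- lmm_auc(fd, auc_spec(c(-0.01, 0.01)), "auc ~ x + (x | id)")
  expect_equal(unname(flmm$beta_tilde[, 1]), auc$estimate, tolerance = 1e-6)
  expect_equal(unname(flmm$se_pointwise[, 1]), auc$se, tolerance = 1e-6)
})

test_that("permutation runs follow the consecutive-threshold rule", {
  set.seed(61)
  S <- 30
  n_subj <- 6
  J <- 10
  id <- rep(sprintf("s%d", 1:n_subj), each = J)
  x <- rep(rep(c(0, 1), each = J / 2), n_subj)
  # strong effect on samples 10..20, none elsewhere
  Y <- matrix(rnorm(n_subj * J * S, sd = 0.3), n_subj * J, S)
  Y[x == 1, 10:20] <- Y[x == 1, 10:20] + 3
  fd <- make_fd_from_matrix(Y, id, x)

  # one-sample rule: runs are exactly the maximal significant blocks
  pt1 <- perm_test(fd, "x", n_permutations = 500, run_rule = 1 / 15, seed = 2)
  sig_blocks <- rle(pt1$significant_pointwise)
  ends <- cumsum(sig_blocks$lengths)
  starts <- ends - sig_blocks$lengths + 1
  expect_equal(pt1$significant_runs$start, starts[sig_blocks$values])
  expect_equal(pt1$significant_runs$end, ends[sig_blocks$values])
  expect_true(any(pt1$significant_runs$start <= 10 &
                    pt1$significant_runs$end >= 20))

  # full criterion at 15 Hz needs ceil(0.5 * 15) = 8 consecutive samples
  pt_full <- perm_test(fd, "x", n_permutations = 500, run_rule = "full",
                       seed = 2)
  expect_equal(pt_full$threshold_samples, 8L)
  expect_equal(perm_test(fd, "x", n_permutations = 500, run_rule = "half",
                         seed = 2)$threshold_samples, 4L)

  # an effect confined to fewer consecutive samples than the threshold
  # is never declared significant under the run rule
  Y2 <- matrix(rnorm(n_subj * J * S, sd = 0.3), n_subj * J, S)
  Y2[x == 1, 14:16] <- Y2[x == 1, 14:16] + 5
  fd2 <- make_fd_from_matrix(Y2, id, x)
  pt2 <- perm_test(fd2, "x", n_permutations = 500, run_rule = "full", seed = 2)
  expect_true(any(pt2$significant_pointwise[14:16]))
  expect_equal(nrow(pt2$significant_runs), 0L)

  expect_error(perm_test(fd, "x", n_permutations = 100), "199")
  # p-values live on the grid k/(n_permutations + 1)
  expect_true(all(abs(pt1$pointwise_p * 501 - round(pt1$pointwise_p * 501)) < 1e-9))
  expect_gte(min(pt1$pointwise_p), 1 / 501)
})

test_that("permutation p-values are conservative under the null with the run rule", {
  set.seed(71)
  R <- 120
  fw_rejections <- 0
  pvals <- c()
  for (r in seq_len(R)) {
    S <- 20
    id <- rep(sprintf("s%d", 1:6), each = 8)
    x <- rep(rep(c(0, 1), each = 4), 6)
    Y <- matrix(rnorm(48 * S), 48, S)
    fd <- make_fd_from_matrix(Y, id, x)
    pt <- perm_test(fd, "x", n_permutations = 199, run_rule = "full",
                    seed = r)
    if (nrow(pt$significant_runs) > 0) fw_rejections <- fw_rejections + 1
    pvals <- c(pvals, pt$pointwise_p)
  }
  # familywise rate with the consecutive-threshold rule sits well below
  # the pointwise alpha
  expect_lt(fw_rejections / R, 0.05)
  # pooled pointwise p-values are roughly uniform on the achievable grid
  expect_equal(mean(pvals), 0.5, tolerance = 0.03)
  expect_equal(mean(pvals <= 0.25), 0.25, tolerance = 0.04)
})

test_that("cluster bootstrap band covers the observed mean difference", {
  fd <- make_toy_fd(n_subj = 6, trials_per_cond = 6, S = 8, seed = 83,
                    re_sd = 0.4)
  ci <- cluster_bootstrap_ci(fd, "x", B = 300, seed = 4)
  expect_equal(nrow(ci), 8)
  expect_true(all(ci$lo <= ci$estimate & ci$estimate <= ci$hi))
})
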