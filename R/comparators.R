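#' Define a trial summary-measure (AUC) window
#'
#' The "area under the curve" summary of a trial is either the mean signal
#' (`mode = "mean"`) or the trapezoidal integral (`mode = "integral"`) over a
#' time window, optionally minus the same summary over a baseline window.
#'
#' @param window Length-2 numeric `(start, end)` in seconds on the trial grid.
#' @param baseline_window Optional length-2 numeric baseline window.
#' @param mode `"mean"` (average signal) or `"integral"` (trapezoid).
#' @return A list of class `auc_spec`.
#' @export
auc_spec <- function(window, baseline_window = NULL,
                     mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!is.null(baseline_window)) {
    stopifnot(length(baseline_window) == 2,
              baseline_window[1] < baseline_window[2])
  }
  structure(list(window = as.numeric(window),
                 baseline_window = if (is.null(baseline_window)) NULL
                                   else as.numeric(baseline_window),
                 mode = mode),
            class = "auc_spec")
}

window_idx <- function(window, time) {
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  if (window[1] < time[1] - dt / 2 || window[2] > time[length(time)] + dt / 2) {
    abort(sprintf("auc window [%.3g, %.3g] lies outside the time grid [%.3g, %.3g]",
                  window[1], window[2], time[1], time[length(time)]))
  }
  i1 <- which.min(abs(time - window[1]))
  i2 <- which.min(abs(time - window[2]))
  i1:i2
}

#' Per-trial AUC summary values
#'
#' @param data An [fd_data()] object.
#' @param spec An [auc_spec()]. Windows are resolved to the nearest grid
#'   samples with inclusive endpoints.
#' @return Numeric vector, one summary per trial.
#' @export
compute_auc <- function(data, spec) {
  stopifnot(inherits(data, "fd_data"), inherits(spec, "auc_spec"))
  sig <- signal_matrix(data)
  time <- time_grid(data)
  summarize <- function(idx) {
    sub <- sig[, idx, drop = FALSE]
    if (spec$mode == "mean") {
      rowMeans(sub)
    } else {
      tt <- time[idx]
      if (length(idx) < 2) abort("compute_auc: integral mode needs >= 2 samples in the window")
      w <- diff(tt)
      as.vector(sub[, -length(idx), drop = FALSE] %*% w / 2 +
                  sub[, -1, drop = FALSE] %*% w / 2)
    }
  }
  out <- summarize(window_idx(spec$window, time))
  if (!is.null(spec$baseline_window)) {
    out <- out - summarize(window_idx(spec$baseline_window, time))
  }
  out
}

#' Paired t-test on subject-level AUC summaries
#'
#' AUC per trial, averaged per subject and condition, then a paired t-test
#' across subjects (df = n_subjects - 1). The difference is taken as the
#' higher condition level minus the lower.
#'
#' @param data An [fd_data()] object.
#' @param spec An [auc_spec()].
#' @param condition Name of a binary covariate column.
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p_value`,
#'   `conf_lo`, `conf_hi`.
#' @export
paired_ttest_auc <- function(data, spec, condition) {
  lv <- check_binary(data, condition)
  df <- tibble::tibble(
    subject = fd_subject(data),
    cond = factor(data[[condition]] == lv[2], levels = c(FALSE, TRUE)),
    auc = compute_auc(data, spec)
  )
  means <- df |>
    dplyr::group_by(.data$subject, .data$cond) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cond", values_from = "auc")
  missing <- means$subject[!stats::complete.cases(means)]
  if (length(missing)) {
    abort(paste0("paired_ttest_auc: subject(s) missing a condition: ",
                 paste(missing, collapse = ", ")))
  }
  d <- means$`TRUE` - means$`FALSE`
  if (sd(d) == 0) {
    abort("paired_ttest_auc: degenerate input, all subject differences are equal (zero pooled SD)")
  }
  tt <- t.test(d)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 conf_lo = tt$conf.int[1], conf_hi = tt$conf.int[2])
}

check_binary <- function(data, condition) {
  v <- data[[condition]]
  if (is.null(v)) abort(paste0("condition column '", condition, "' not found"))
  lv <- sort(unique(v))
  if (length(lv) != 2) {
    abort(paste0("condition '", condition, "' must be binary; found ",
                 length(lv), " levels"))
  }
  lv
}

#' Linear mixed model on trial-level AUC summaries
#'
#' Fits a scalar mixed model to per-trial AUCs with the same formula grammar
#' as [fit_flmm()], e.g. `"auc ~ x + (x | id)"`, and reports Wald (normal)
#' inference on the fixed effects.
#'
#' @param data An [fd_data()] object.
#' @param spec An [auc_spec()].
#' @param formula Mixed-model formula with response `auc`.
#' @return A tibble with one row per fixed effect: `term`, `estimate`, `se`,
#'   `statistic`, `p_value`, `conf_lo`, `conf_hi`; attribute `"fit"` carries
#'   the lme4 fit.
#' @export
lmm_auc <- function(data, spec, formula = "auc ~ x + (x | id)") {
  fspec <- if (inherits(formula, "flmm_formula")) formula else parse_formula(formula)
  cov_df <- tibble::as_tibble(data)[setdiff(names(data),
                                            attr(data, "signal_cols"))]
  cov_df$auc <- compute_auc(data, spec)
  fspec2 <- fspec
  fspec2$response <- "auc"
  df <- cov_df
  df$.y <- df$auc
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(lmer_formula(fspec2), data = df, REML = TRUE,
                    control = ctrl)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- fe / se
  out <- tibble::tibble(term = names(fe), estimate = unname(fe),
                        se = unname(se), statistic = unname(z),
                        p_value = 2 * pnorm(-abs(unname(z))),
                        conf_lo = unname(fe - qnorm(0.975) * se),
                        conf_hi = unname(fe + qnorm(0.975) * se))
  attr(out, "fit") <- fit
  out
}

#' Within-subject permutation test with a consecutive-threshold criterion
#'
#' At each time-point the observed statistic is the condition mean difference
#' (higher level minus lower). The permutation distribution is generated by
#' flipping each subject's condition assignment independently with
#' probability 1/2 (a subject-level sign flip that respects the
#' repeated-measures structure). Two-sided pointwise p-values have resolution
#' `1/(n_permutations + 1)`. Significant runs are maximal blocks of
#' consecutively significant time-points whose duration reaches the run rule:
#' `"full"` = 0.5 s, `"half"` = 0.25 s of consecutive significance (converted
#' to samples at the grid rate, rounding up), or a numeric duration in
#' seconds.
#'
#' @param data An [fd_data()] object.
#' @param condition Name of a binary covariate column.
#' @param n_permutations Number of label permutations (>= 199).
#' @param alpha Pointwise significance level (default 0.05).
#' @param run_rule `"full"`, `"half"` or a duration in seconds.
#' @param seed Integer seed for the permutation draws.
#' @return A list of class `flmm_perm`: `pointwise_p`,
#'   `significant_pointwise`, `significant_runs` (tibble of start/end
#'   indices), `observed` statistic curve, `n_permutations`,
#'   `threshold_samples`.
#' @export
perm_test <- function(data, condition, n_permutations = 1000, alpha = 0.05,
                      run_rule = "full", seed = 1L) {
  stopifnot(inherits(data, "fd_data"))
  if (n_permutations < 199) {
    abort("perm_test: n_permutations must be at least 199")
  }
  lv <- check_binary(data, condition)
  x <- data[[condition]] == lv[2]
  Y <- signal_matrix(data)
  time <- time_grid(data)
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  rate_hz <- 1 / dt
  dur <- if (identical(run_rule, "full")) 0.5
         else if (identical(run_rule, "half")) 0.25
         else as.numeric(run_rule)
  thr <- max(1L, as.integer(ceiling(dur * rate_hz)))

  subj <- fd_subject(data)
  subj_i <- as.integer(droplevels(subj))
  n_subj <- max(subj_i)
  mean_diff <- function(xx) colMeans(Y[xx, , drop = FALSE]) -
    colMeans(Y[!xx, , drop = FALSE])
  obs <- mean_diff(x)

  set.seed(seed)
  exceed <- numeric(ncol(Y))
  for (b in seq_len(n_permutations)) {
    flip <- runif(n_subj) < 0.5
    xx <- xor(x, flip[subj_i])
    if (all(xx) || all(!xx)) xx <- x  # degenerate flip; keep labels
    exceed <- exceed + (abs(mean_diff(xx)) >= abs(obs) - 1e-12)
  }
  p <- (1 + exceed) / (n_permutations + 1)
  sig <- p <= alpha

  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= thr
  significant_runs <- tibble::tibble(start = starts[keep], end = ends[keep])

  structure(list(pointwise_p = p, significant_pointwise = sig,
                 significant_runs = significant_runs, observed = obs,
                 n_permutations = n_permutations, alpha = alpha,
                 threshold_samples = thr, time_grid = time),
            class = "flmm_perm")
}

#' @export
print.flmm_perm <- function(x, ...) {
  cat(sprintf("<flmm_perm> %d permutations, alpha = %g, run threshold = %d sample(s)\n",
              x$n_permutations, x$alpha, x$threshold_samples))
  if (nrow(x$significant_runs)) {
    cat("  significant runs (sample indices):\n")
    print(x$significant_runs)
  } else cat("  no significant runs\n")
  invisible(x)
}

#' Subject-level cluster bootstrap band for the condition mean difference
#'
#' Resamples subjects with replacement and recomputes the pointwise condition
#' mean-difference curve; returns percentile pointwise confidence limits.
#' Used to attach pointwise intervals to the permutation comparator.
#'
#' @param data An [fd_data()] object.
#' @param condition Binary covariate column name.
#' @param B Bootstrap resamples (default 500).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return A tibble with `s`, `time`, `estimate`, `lo`, `hi`.
#' @export
cluster_bootstrap_ci <- function(data, condition, B = 500, level = 0.95,
                                 seed = 1L) {
  lv <- check_binary(data, condition)
  x <- data[[condition]] == lv[2]
  Y <- signal_matrix(data)
  subj <- droplevels(fd_subject(data))
  rows <- split(seq_along(subj), subj)
  n_subj <- length(rows)
  set.seed(seed)
  stat <- function(r) {
    xx <- x[r]
    colMeans(Y[r[xx], , drop = FALSE]) - colMeans(Y[r[!xx], , drop = FALSE])
  }
  obs <- stat(seq_along(subj))
  boot <- matrix(NA_real_, B, ncol(Y))
  for (b in seq_len(B)) {
    pick <- sample.int(n_subj, n_subj, replace = TRUE)
    boot[b, ] <- stat(unlist(rows[pick], use.names = FALSE))
  }
  a <- (1 - level) / 2
  tibble::tibble(s = seq_len(ncol(Y)), time = time_grid(data), estimate = obs,
                 lo = apply(boot, 2, quantile, a, na.rm = TRUE),
                 hi = apply(boot, 2, quantile, 1 - a, na.rm = TRUE))
}
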