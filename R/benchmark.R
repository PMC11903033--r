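#' Replicated-simulation benchmark of coverage and power
#'
#' For each sample size in `n_grid` and each of `R` replicates, draws a
#' dataset from the generative model, runs every requested method, and scores:
#' joint coverage (the joint band contains the true effect curve at every
#' time-point simultaneously), pointwise coverage (per-time-point containment
#' averaged over the cue-period time-points), and cue-period power. Power is:
#' for the functional model, the joint band excluding zero somewhere in the
#' cue period; for the permutation comparator, a surviving consecutive run
#' intersecting the cue period; for the t-test and the AUC mixed model,
#' p < 0.05. The summary methods analyze the cue-period mean signal (AUC), so
#' their "pointwise" coverage is containment of the cue-period mean of the
#' true effect by their interval, one indicator per replicate.
#'
#' @param config A [sim_config()]; `n_subjects` is overridden by `n_grid`.
#' @param n_grid Sample sizes to benchmark (default `c(4, 7, 10, 14)`).
#' @param R Replicates per sample size (default 200; at least 50 recommended).
#' @param methods Character subset of `c("flmm", "perm", "ttest", "lmm")`, or
#'   a named list of scoring functions `function(sim, truth, cue_idx)`
#'   returning `list(joint_cover=, pw_cover=, signif=)` (used for harness
#'   self-tests).
#' @param seed Integer base seed; replicates are seed-streamed for
#'   reproducibility and restartability.
#' @param cue_window Optional `(start, end)` seconds; defaults to the window
#'   where the configured true effect is nonzero.
#' @param control [flmm_control()] for the functional fits.
#' @param perm_n_permutations,perm_boot_B Permutation-count and bootstrap
#'   resamples for the permutation comparator.
#' @return A tibble of class `flmm_benchmark`: one row per (method, n) with
#'   coverages, power, Monte-Carlo standard errors and failure counts.
#' @export
run_benchmark <- function(config, n_grid = c(4, 7, 10, 14), R = 200,
                          methods = c("flmm", "perm", "ttest", "lmm"),
                          seed = 1L, cue_window = NULL,
                          control = flmm_control(smooth_blups = FALSE),
                          perm_n_permutations = 199, perm_boot_B = 500) {
  stopifnot(inherits(config, "sim_config"), R >= 1)
  cue_idx <- if (is.null(cue_window)) which(config$beta1 != 0)
             else window_idx(cue_window, (seq_len(config$S) - 1) / config$rate_hz)
  if (!length(cue_idx)) abort("run_benchmark: empty cue period")

  scorers <- resolve_methods(methods, control, perm_n_permutations,
                             perm_boot_B)
  if (!length(scorers)) {
    out <- tibble::tibble(method = character(), n_subjects = integer(),
                          joint_coverage = numeric(), joint_mc_se = numeric(),
                          pointwise_coverage = numeric(),
                          pointwise_mc_se = numeric(),
                          power = numeric(), power_mc_se = numeric(),
                          n_replicates = integer(), n_failed = integer())
    class(out) <- c("flmm_benchmark", class(out))
    return(out)
  }

  res <- list()
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    cfg <- config
    cfg$n_subjects <- n
    scores <- lapply(scorers, function(f) {
      list(joint = logical(0), pw = numeric(0), sig = logical(0), fail = 0L)
    })
    for (r in seq_len(R)) {
      rep_seed <- (seed + 15485863L * (ni - 1L) + 2654435L * r) %% 2147483647L
      sim <- simulate_dataset(cfg, seed = rep_seed)
      for (m in names(scorers)) {
        sc <- tryCatch(scorers[[m]](sim, sim$truth, cue_idx),
                       error = function(e) NULL)
        if (is.null(sc)) {
          scores[[m]]$fail <- scores[[m]]$fail + 1L
        } else {
          scores[[m]]$joint <- c(scores[[m]]$joint, sc$joint_cover)
          scores[[m]]$pw <- c(scores[[m]]$pw, sc$pw_cover)
          scores[[m]]$sig <- c(scores[[m]]$sig, sc$signif)
        }
      }
    }
    for (m in names(scorers)) {
      if (scores[[m]]$fail > 0.2 * R) {
        abort(sprintf("run_benchmark: method '%s' failed on %d/%d replicates at n=%d",
                      m, scores[[m]]$fail, R, n))
      }
      Rm <- R - scores[[m]]$fail
      pj <- mean(scores[[m]]$joint)
      pp <- mean(scores[[m]]$pw)
      po <- mean(scores[[m]]$sig)
      res[[length(res) + 1]] <- tibble::tibble(
        method = m, n_subjects = n,
        joint_coverage = pj, joint_mc_se = sqrt(pj * (1 - pj) / Rm),
        pointwise_coverage = pp,
        pointwise_mc_se = sd(scores[[m]]$pw) / sqrt(Rm),
        power = po, power_mc_se = sqrt(po * (1 - po) / Rm),
        n_replicates = Rm, n_failed = scores[[m]]$fail)
    }
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("flmm_benchmark", class(out))
  attr(out, "cue_idx") <- cue_idx
  out
}

resolve_methods <- function(methods, control, perm_n_permutations,
                            perm_boot_B) {
  if (is.list(methods)) {
    if (length(methods) && is.null(names(methods))) {
      abort("run_benchmark: a list of methods must be named")
    }
    return(methods)
  }
  builtin <- list(
    flmm = function(sim, truth, cue_idx) {
      fit <- fit_flmm(sim$data, "y ~ x + (x | id)", control = control)
      td <- tidy(fit)
      eff <- td[td$term == "x", ]
      covered <- truth$beta1 >= eff$joint_lo & truth$beta1 <= eff$joint_hi
      pw <- truth$beta1 >= eff$pointwise_lo & truth$beta1 <= eff$pointwise_hi
      excl0 <- eff$joint_lo[cue_idx] > 0 | eff$joint_hi[cue_idx] < 0
      list(joint_cover = all(covered), pw_cover = mean(pw[cue_idx]),
           signif = any(excl0))
    },
    perm = function(sim, truth, cue_idx) {
      pt <- perm_test(sim$data, "x", n_permutations = perm_n_permutations,
                      seed = 1L)
      ci <- cluster_bootstrap_ci(sim$data, "x", B = perm_boot_B, seed = 1L)
      covered <- truth$beta1 >= ci$lo & truth$beta1 <= ci$hi
      hit <- nrow(pt$significant_runs) > 0 &&
        any(pt$significant_runs$start <= max(cue_idx) &
              pt$significant_runs$end >= min(cue_idx))
      list(joint_cover = all(covered), pw_cover = mean(covered[cue_idx]),
           signif = hit)
    },
    ttest = function(sim, truth, cue_idx) {
      aspec <- auc_spec(range(truth$time[cue_idx]), mode = "mean")
      tt <- paired_ttest_auc(sim$data, aspec, "x")
      target <- mean(truth$beta1[cue_idx])
      cover <- target >= tt$conf_lo & target <= tt$conf_hi
      list(joint_cover = cover, pw_cover = as.numeric(cover),
           signif = tt$p_value < 0.05)
    },
    lmm = function(sim, truth, cue_idx) {
      aspec <- auc_spec(range(truth$time[cue_idx]), mode = "mean")
      lm <- lmm_auc(sim$data, aspec, "auc ~ x + (x | id)")
      row <- lm[lm$term == "x", ]
      target <- mean(truth$beta1[cue_idx])
      cover <- target >= row$conf_lo & target <= row$conf_hi
      list(joint_cover = cover, pw_cover = as.numeric(cover),
           signif = row$p_value < 0.05)
    }
  )
  unknown <- setdiff(methods, names(builtin))
  if (length(unknown)) {
    abort(paste0("run_benchmark: unknown method(s): ",
                 paste(unknown, collapse = ", ")))
  }
  builtin[methods]
}

#' Write benchmark results and summary figures
#'
#' Writes `results.csv` plus `coverage.png` and `power.png` (coverage and
#' power versus sample size per method, with Monte-Carlo error bars) to
#' `out_dir`. An empty result writes an empty table and no plots.
#'
#' @param result A [run_benchmark()] tibble.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report <- function(result, out_dir) {
  stopifnot(inherits(result, "flmm_benchmark"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "results.csv")
  readr::write_csv(tibble::as_tibble(result), csv, progress = FALSE)
  paths <- csv
  if (nrow(result)) {
    cov_p <- file.path(out_dir, "coverage.png")
    pow_p <- file.path(out_dir, "power.png")
    ggplot2::ggsave(cov_p, plot_benchmark(result, "coverage"),
                    width = 7, height = 4, dpi = 120)
    ggplot2::ggsave(pow_p, plot_benchmark(result, "power"),
                    width = 7, height = 4, dpi = 120)
    paths <- c(paths, cov_p, pow_p)
  }
  invisible(paths)
}

#' Re-read a written benchmark table
#'
#' @param path Path to a `results.csv` written by [report()].
#' @return A `flmm_benchmark` tibble.
#' @export
read_benchmark_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("flmm_benchmark", class(out))
  out
}

plot_benchmark <- function(result, what = c("coverage", "power")) {
  what <- match.arg(what)
  df <- tibble::as_tibble(result)
  if (what == "coverage") {
    long <- dplyr::bind_rows(
      dplyr::transmute(df, method = .data$method, n_subjects = .data$n_subjects,
                       panel = "joint coverage", value = .data$joint_coverage,
                       se = .data$joint_mc_se),
      dplyr::transmute(df, method = .data$method, n_subjects = .data$n_subjects,
                       panel = "pointwise coverage (cue period)",
                       value = .data$pointwise_coverage,
                       se = .data$pointwise_mc_se))
    ref <- 0.95
  } else {
    long <- dplyr::transmute(df, method = .data$method,
                             n_subjects = .data$n_subjects, panel = "power",
                             value = .data$power, se = .data$power_mc_se)
    ref <- NA_real_
  }
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n_subjects,
                                           y = .data$value,
                                           colour = .data$method,
                                           group = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - 2 * .data$se,
                                        ymax = .data$value + 2 * .data$se),
                           width = 0.3) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subjects", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(ref)) {
    gg <- gg + ggplot2::geom_hline(yintercept = ref, linetype = 2,
                                   colour = "grey40")
  }
  gg
}

#' @method autoplot flmm_benchmark
#' @export
autoplot.flmm_benchmark <- function(object, what = "coverage", ...) {
  plot_benchmark(object, what)
}
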