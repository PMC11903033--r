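#' Stationary covariance kernels on the trial time grid
#'
#' `se_kernel()` is the squared-exponential (Gaussian-process) kernel
#' `v * exp(-(t1-t2)^2 / (2 l^2))`; `ou_kernel()` the Ornstein-Uhlenbeck
#' (exponential) kernel `v * exp(-|t1-t2| / l)`, used for temporally
#' correlated trial noise.
#'
#' @param times Numeric vector of sample times (seconds).
#' @param variance Marginal variance `v`.
#' @param length_scale Correlation length `l` in seconds.
#' @return An S x S positive semidefinite matrix.
#' @export
se_kernel <- function(times, variance = 1, length_scale = 0.5) {
  d <- outer(times, times, "-")
  variance * exp(-d^2 / (2 * length_scale^2))
}

#' @rdname se_kernel
#' @export
ou_kernel <- function(times, variance = 1, length_scale = 0.3) {
  d <- abs(outer(times, times, "-"))
  variance * exp(-d / length_scale)
}

#' Default ground truth for the simulation study
#'
#' Parametric stand-ins for the data-derived truth of the delay-lengthening
#' design: a cue-response-shaped functional intercept (fast-rising,
#' slow-decaying transient peaking near 1.5), a binary-condition effect that
#' is zero over the first quarter of the trial and dips to -0.5 over a
#' mid-trial window (a late relative reduction), squared-exponential kernels
#' for the functional random intercept and slope, and an Ornstein-Uhlenbeck
#' error kernel. Amplitudes are chosen so the effect is buried in noise at
#' trial level but clear in session averages.
#'
#' @param S Number of time-points (at least 10).
#' @param rate_hz Sampling rate (default 15 samples/sec).
#' @return A list with `beta0`, `beta1` (length-S), kernels `K_gamma0`,
#'   `K_gamma1`, `K_eps`, the `time` grid, and the cue-period window
#'   (`cue_idx`, indices where `beta1` is nonzero).
#' @export
default_truth <- function(S, rate_hz = 15) {
  stopifnot(S >= 10)
  time <- (seq_len(S) - 1) / rate_hz
  Tend <- time[S]
  tp <- 0.2 * Tend
  beta0 <- 1.5 * (time / tp) * exp(1 - time / tp)
  a <- 0.3 * Tend
  b <- 0.75 * Tend
  beta1 <- ifelse(time > a & time < b,
                  -0.5 * sin(pi * (time - a) / (b - a))^2, 0)
  list(
    beta0 = beta0,
    beta1 = beta1,
    K_gamma0 = se_kernel(time, variance = 0.25, length_scale = 0.5),
    K_gamma1 = se_kernel(time, variance = 0.0225, length_scale = 0.5),
    K_eps = ou_kernel(time, variance = 0.25, length_scale = 0.3),
    time = time,
    cue_idx = which(beta1 != 0),
    cue_window = c(a, b)
  )
}

#' Parameterization of the synthetic generative model
#'
#' The generator draws, per subject, functional random intercept and slope
#' curves from Gaussian processes, and per trial a temporally correlated error
#' curve, then assembles
#' `Y = beta0(s) + gamma0_i(s) + x * (beta1(s) + gamma1_i(s)) + eps(s)`.
#' The error covariance is `eps_scale * K_eps` (default multiplier 5) with a
#' mild per-subject lognormal scale jitter emulating between-animal noise
#' heterogeneity. Errors are independent across trials and subjects.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_condition Trials per condition per subject (binary
#'   covariate; for a continuous covariate the subject receives
#'   `2 * trials_per_condition` trials).
#' @param S Time-points per trial.
#' @param rate_hz Sampling rate in samples/sec (default 15).
#' @param beta0,beta1 True coefficient functions (default: [default_truth()]).
#' @param K_gamma0,K_gamma1,K_eps PSD kernels (default: [default_truth()]).
#' @param eps_scale Multiplier on `K_eps` (default 5).
#' @param covariate_type `"binary"` (balanced within subject) or
#'   `"continuous"` (standard normal per trial).
#' @param noise_jitter_sd Lognormal sd of the per-subject error-scale jitter
#'   (default 0.15; set 0 to disable).
#' @param share_error_kernel_groups If `TRUE`, only 7 distinct error scales
#'   are drawn and recycled across subjects (first 7 subjects take them in
#'   order when `n_subjects > 7`, the rest resample), mimicking reuse of a
#'   small pool of per-animal error covariances.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 7, trials_per_condition = 25, S = 40,
                       rate_hz = 15, beta0 = NULL, beta1 = NULL,
                       K_gamma0 = NULL, K_gamma1 = NULL, K_eps = NULL,
                       eps_scale = 5, covariate_type = c("binary", "continuous"),
                       noise_jitter_sd = 0.15,
                       share_error_kernel_groups = FALSE, seed = 1L) {
  covariate_type <- match.arg(covariate_type)
  stopifnot(n_subjects >= 1, trials_per_condition >= 1, S >= 1)
  truth <- if (is.null(beta0) || is.null(beta1) || is.null(K_gamma0) ||
               is.null(K_gamma1) || is.null(K_eps)) {
    default_truth(S, rate_hz)
  } else NULL
  structure(list(
    n_subjects = n_subjects, trials_per_condition = trials_per_condition,
    S = S, rate_hz = rate_hz,
    beta0 = beta0 %||% truth$beta0, beta1 = beta1 %||% truth$beta1,
    K_gamma0 = K_gamma0 %||% truth$K_gamma0,
    K_gamma1 = K_gamma1 %||% truth$K_gamma1,
    K_eps = K_eps %||% truth$K_eps,
    eps_scale = eps_scale, covariate_type = covariate_type,
    noise_jitter_sd = noise_jitter_sd,
    share_error_kernel_groups = share_error_kernel_groups,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# matrix square root of a PSD kernel; errors on genuinely indefinite input
kernel_sqrt <- function(K, name) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values), 1)
  if (min(eg$values) < -tol) {
    abort(paste0("simulate_dataset: kernel '", name, "' is not positive ",
                 "semidefinite (min eigenvalue ", format(min(eg$values)), ")"))
  }
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

draw_gp <- function(n, sqrtK) {
  if (n == 0) return(matrix(0, 0, nrow(sqrtK)))
  matrix(rnorm(n * nrow(sqrtK)), n) %*% sqrtK
}

#' Simulate a functional dataset from the generative model
#'
#' @param config A [sim_config()] list.
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `data` (an [fd_data()] with covariate `x` and subject
#'   column `id`) and `truth` (the true `beta0`, `beta1`, per-subject `gamma0`
#'   and `gamma1` curves, and the cue-period index).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  S <- config$S
  n <- config$n_subjects
  Jc <- config$trials_per_condition
  sq_g0 <- kernel_sqrt(config$K_gamma0, "K_gamma0")
  sq_g1 <- kernel_sqrt(config$K_gamma1, "K_gamma1")
  sq_e <- kernel_sqrt(config$eps_scale * config$K_eps, "K_eps")

  gamma0 <- draw_gp(n, sq_g0)
  gamma1 <- draw_gp(n, sq_g1)

  scales <- if (config$noise_jitter_sd > 0) {
    if (config$share_error_kernel_groups) {
      pool <- exp(rnorm(7, 0, config$noise_jitter_sd))
      m <- if (n <= 7) sample.int(7, n) else {
        c(1:7, sample.int(7, n - 7, replace = n - 7 > 7))
      }
      pool[m]
    } else exp(rnorm(n, 0, config$noise_jitter_sd))
  } else rep(1, n)

  J <- 2 * Jc
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- if (config$covariate_type == "binary") rep(c(0, 1), each = Jc)
         else rnorm(J)
    eps <- scales[i] * draw_gp(J, sq_e)
    Yi <- matrix(config$beta0, J, S, byrow = TRUE) +
      matrix(gamma0[i, ], J, S, byrow = TRUE) +
      x %o% (config$beta1) + x %o% gamma1[i, ] + eps
    rows[[i]] <- tibble::tibble(id = sprintf("subj%02d", i), x = x,
                                as.data.frame(Yi))
  }
  df <- dplyr::bind_rows(rows)
  names(df)[-(1:2)] <- paste0("y_", seq_len(S))
  time <- (seq_len(S) - 1) / config$rate_hz
  data <- fd_data(df, signal_cols = paste0("y_", seq_len(S)),
                  time_grid = time, subject = "id")
  list(
    data = data,
    truth = list(beta0 = config$beta0, beta1 = config$beta1,
                 gamma0 = gamma0, gamma1 = gamma1,
                 cue_idx = which(config$beta1 != 0), time = time,
                 noise_scales = scales)
  )
}

#' Simulate a nested session/trial design with an inter-reward-interval
#' covariate
#'
#' Emulates a random-reward task: each subject runs several sessions of
#' `trials_per_session` reward deliveries; the inter-reward interval (IRI) is
#' exponential with mean 14 s and the latency from reward to first lick is
#' gamma-distributed with mean 1 s. Signals carry subject- and session-level
#' functional random intercepts, subject- and session-level random
#' lick-latency slopes, and correlated trial noise. The IRI covariate has no
#' effect on the signal unless `iri_effect` is supplied, so the design can be
#' used for type-I-error checks of the nested-model formulas.
#'
#' @param n_subjects,sessions,trials_per_session Design sizes (all >= 1).
#' @param seed Integer seed.
#' @param S,rate_hz Trial grid.
#' @param iri_effect Optional length-S functional effect of (centered) IRI.
#' @return A list with `data` (fd_data with covariates `iri`, `lick_latency`,
#'   `trial`, `session_num` and grouping columns `id`, `session`) and `truth`.
#' @export
simulate_iri_design <- function(n_subjects = 6, sessions = 3,
                                trials_per_session = 100, seed = 1L,
                                S = 40, rate_hz = 15, iri_effect = NULL) {
  stopifnot(n_subjects >= 1, sessions >= 1, trials_per_session >= 1)
  set.seed(seed)
  time <- (seq_len(S) - 1) / rate_hz
  Tend <- time[S]
  tp <- 0.2 * max(Tend, 1e-6)
  beta0 <- 1.2 * (time / tp) * exp(1 - time / tp)
  sq_subj <- kernel_sqrt(se_kernel(time, 0.2^2, 0.5), "K_subject")
  sq_sess <- kernel_sqrt(se_kernel(time, 0.1^2, 0.5), "K_session")
  sq_lick_subj <- kernel_sqrt(se_kernel(time, 0.1^2, 0.5), "K_lick_subject")
  sq_lick_sess <- kernel_sqrt(se_kernel(time, 0.05^2, 0.5), "K_lick_session")
  sq_e <- kernel_sqrt(ou_kernel(time, 0.5^2, 0.3), "K_eps")

  rows <- vector("list", n_subjects * sessions)
  r <- 0
  for (i in seq_len(n_subjects)) {
    id <- sprintf("subj%02d", i)
    g0 <- drop(draw_gp(1, sq_subj))
    g2 <- drop(draw_gp(1, sq_lick_subj))
    for (l in seq_len(sessions)) {
      g1 <- drop(draw_gp(1, sq_sess))
      g3 <- drop(draw_gp(1, sq_lick_sess))
      J <- trials_per_session
      iri <- stats::rexp(J, rate = 1 / 14)
      lick <- stats::rgamma(J, shape = 4, scale = 0.25)
      lick_c <- lick - 1  # latencies enter centered at their 1 s mean
      eps <- draw_gp(J, sq_e)
      Yi <- matrix(beta0 + g0 + g1, J, S, byrow = TRUE) +
        lick_c %o% (g2 + g3) + eps
      if (!is.null(iri_effect)) Yi <- Yi + (iri - 14) %o% iri_effect
      r <- r + 1
      rows[[r]] <- tibble::tibble(
        id = id, session = sprintf("%s_s%02d", id, l),
        session_num = l, trial = seq_len(J),
        iri = iri, lick_latency = lick, as.data.frame(Yi))
    }
  }
  df <- dplyr::bind_rows(rows)
  sig <- paste0("y_", seq_len(S))
  names(df)[-(1:6)] <- sig
  data <- fd_data(df, signal_cols = sig, time_grid = time,
                  subject = "id", session = "session")
  list(data = data,
       truth = list(beta0 = beta0, iri_effect = iri_effect %||% rep(0, S),
                    time = time))
}
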