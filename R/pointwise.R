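#' Fit one linear mixed model per trial time-point
#'
#' Massively univariate estimation: for every time-point `s` of the trial
#' grid, the signal values across all trials are regressed on the trial
#' covariates with a Gaussian linear mixed model, estimated by REML. Fits are
#' independent across `s`; the implementation walks the grid warm-starting
#' each fit from its neighbour purely for speed, which does not change the
#' estimates. Random-effect covariance within a block is unstructured;
#' variance components on the boundary (zero) are accepted.
#'
#' Time-points where the optimizer fails are refit once from perturbed
#' starting values; if still failing they are flagged non-converged (not
#' fatal) and later imputed by the smoother.
#'
#' @param data An [fd_data()] object.
#' @param spec A [parse_formula()] result or a formula string. The response
#'   name is bound to the signal columns of `data`.
#' @param control A [flmm_control()] list.
#' @return An object of class `flmm_pointwise` with elements `beta_hat`
#'   (p x S), `vcov` (p x p x S Wald covariances), `sigma2` (S), `G_hat`
#'   (per random block, q x q x S REML covariance), `blups` (per block,
#'   levels x q x S), `resid` (N x S conditional residuals), `converged`,
#'   `reml_loglik`, `aic`, `bic`, plus the design pieces reused by the
#'   inference stage.
#' @export
fit_pointwise <- function(data, spec, control = flmm_control()) {
  stopifnot(inherits(data, "fd_data"))
  if (!inherits(spec, "flmm_formula")) spec <- parse_formula(spec)
  if (!identical(control$family, "gaussian")) {
    abort(paste0("fit_pointwise: family '", control$family,
                 "' not implemented; only 'gaussian' is supported"))
  }

  Y <- signal_matrix(data)
  S <- ncol(Y)
  N <- nrow(Y)
  subj <- fd_subject(data)

  cov_df <- tibble::as_tibble(data)[setdiff(names(data), attr(data, "signal_cols"))]
  spec <- drop_degenerate_blocks(spec, cov_df)
  design <- build_design(spec, cov_df, center = control$center)
  df <- design$data

  # grouping factors must have >= 2 levels and nest within subject
  for (b in design$blocks) {
    if (nlevels(droplevels(b$group)) < 2L) {
      abort(paste0("fit_pointwise: grouping factor '", b$grouping,
                   "' has fewer than 2 levels"))
    }
    n_subj <- tapply(subj, b$group, function(x) length(unique(x)))
    if (any(n_subj > 1, na.rm = TRUE)) {
      abort(paste0("fit_pointwise: grouping factor '", b$grouping,
                   "' crosses subjects; random effects must nest in subject"))
    }
  }

  p <- ncol(design$X)
  form <- lmer_formula(spec)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")

  beta_hat <- matrix(NA_real_, p, S, dimnames = list(colnames(design$X), NULL))
  vcov_arr <- array(NA_real_, c(p, p, S))
  sigma2 <- rep(NA_real_, S)
  converged <- logical(S)
  reml_loglik <- rep(NA_real_, S)
  aic <- rep(NA_real_, S)
  bic <- rep(NA_real_, S)
  resid_mat <- matrix(NA_real_, N, S)
  G_hat <- lapply(design$blocks, function(b) {
    q <- ncol(b$Z)
    array(NA_real_, c(q, q, S), dimnames = list(b$colnames, b$colnames, NULL))
  })
  blups <- lapply(design$blocks, function(b) {
    array(NA_real_, c(nlevels(b$group), ncol(b$Z), S),
          dimnames = list(levels(b$group), b$colnames, NULL))
  })
  names(G_hat) <- names(blups) <- vapply(design$blocks, `[[`, character(1),
                                         "grouping")

  # build the model structure once; each time-point only swaps the response
  # and re-optimizes, warm-started from the neighbouring time-point
  quiet <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  df$.y <- Y[, 1]
  lf <- tryCatch(quiet(lme4::lFormula(form, data = df, REML = TRUE,
                                      control = ctrl)),
                 error = function(e) abort(conditionMessage(e)))
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  denv <- environment(devfun)
  theta0 <- ifelse(lf$reTrms$lower == 0, 1, 0)  # lme4's default start
  th <- NULL
  opt1 <- function(start) {
    tryCatch(
      quiet(lme4::optimizeLmer(devfun, optimizer = "nloptwrap", start = start,
                               control = ctrl$optCtrl, calc.derivs = FALSE)),
      error = function(e) NULL)
  }
  for (s in seq_len(S)) {
    denv$resp$setResp(Y[, s])
    # optimize from the warm start and from the default start, keeping the
    # better criterion: warm starts near a variance boundary can stall the
    # optimizer at an inferior stationary point
    opt <- opt1(if (is.null(th)) theta0 else th)
    if (!is.null(th)) {
      opt_b <- opt1(theta0)
      if (!is.null(opt_b) && (is.null(opt) || opt_b$fval < opt$fval)) {
        opt <- opt_b
      }
    }
    if (is.null(opt)) {  # retry from perturbed start values
      opt <- opt1(abs(theta0 + runif(length(theta0), 0, 0.1)))
    }
    if (is.null(opt)) {  # last resort: a fresh fit from scratch
      df$.y <- Y[, s]
      fit <- fit_one_lmm(form, df, ctrl)
      if (is.null(fit)) next  # non-converged, already flagged by NA entries
    } else {
      th <- opt$par
      devfun(opt$par)  # leave the factorization at the optimum
      fit <- lme4::mkMerMod(denv, opt, lf$reTrms, fr = lf$fr)
    }

    ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
    fe <- lme4::fixef(fit)
    if (!all(is.finite(fe))) ok <- FALSE
    converged[s] <- ok
    beta_hat[, s] <- fe
    vcov_arr[, , s] <- as.matrix(vcov(fit))
    sigma2[s] <- sigma(fit)^2
    reml_loglik[s] <- as.numeric(logLik(fit))
    aic[s] <- AIC(fit)
    bic[s] <- BIC(fit)
    resid_mat[, s] <- stats::residuals(fit)

    vc <- lme4::VarCorr(fit)
    re <- lme4::ranef(fit)
    for (bi in seq_along(design$blocks)) {
      gname <- design$blocks[[bi]]$grouping
      Gb <- as.matrix(vc[[gname]])
      cols <- design$blocks[[bi]]$colnames
      G_hat[[bi]][, , s] <- Gb[cols, cols, drop = FALSE]
      reb <- re[[gname]]
      blups[[bi]][rownames(reb), cols, s] <- as.matrix(reb[, cols, drop = FALSE])
    }
  }

  if (!any(converged)) {
    abort("fit_pointwise: no time-point converged; check the model specification")
  }

  structure(list(
    beta_hat = beta_hat, vcov = vcov_arr, sigma2 = sigma2, G_hat = G_hat,
    blups = blups, resid = resid_mat, converged = converged,
    reml_loglik = reml_loglik, aic = aic, bic = bic,
    spec = spec, control = control, design = design, Y = Y, subject = subj,
    time_grid = time_grid(data)
  ), class = "flmm_pointwise")
}

# fresh single-LMM fit used as a fallback when the shared-structure
# optimization fails at a time-point; returns NULL on failure
fit_one_lmm <- function(form, df, ctrl) {
  quiet <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
  tryCatch(quiet(lme4::lmer(form, data = df, REML = TRUE, control = ctrl)),
           error = function(e) NULL)
}

# degenerate nesting: if a nested grouping g1:g2 has exactly one level per
# level of g1 it duplicates the g1 block; drop it with a warning
drop_degenerate_blocks <- function(spec, data) {
  keep <- rep(TRUE, length(spec$blocks))
  for (bi in seq_along(spec$blocks)) {
    g <- spec$blocks[[bi]]$grouping
    gvars <- strsplit(g, ":", fixed = TRUE)[[1]]
    if (length(gvars) == 2L && all(gvars %in% names(data))) {
      inter <- droplevels(interaction(data[gvars], sep = ":", lex.order = TRUE))
      outer <- droplevels(as_sorted_factor(data[[gvars[1]]]))
      if (nlevels(inter) == nlevels(outer)) {
        warn(paste0("dropping random block grouped by '", g,
                    "': one '", gvars[2], "' level per '", gvars[1],
                    "' level makes it indistinguishable from the '",
                    gvars[1], "' block"))
        keep[bi] <- FALSE
      }
    }
  }
  spec$blocks <- spec$blocks[keep]
  spec
}

#' Summed information criteria of a pointwise fit
#'
#' Sums the per-time-point REML AIC and BIC over the converged time-points.
#' These are relative model-comparison scores: comparable only across models
#' fit to the same data with the same converged set.
#'
#' @param fit A [fit_pointwise()] object.
#' @return A tibble with columns `aic`, `bic` and `n_timepoints`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "flmm_pointwise"))
  idx <- which(fit$converged)
  if (!length(idx)) abort("information_criteria: no converged time-points")
  tibble::tibble(aic = sum(fit$aic[idx]), bic = sum(fit$bic[idx]),
                 n_timepoints = length(idx))
}

#' @export
print.flmm_pointwise <- function(x, ...) {
  cat(sprintf("<flmm_pointwise> %d coefficient(s) x %d time-points; %d/%d converged\n",
              nrow(x$beta_hat), ncol(x$beta_hat), sum(x$converged),
              length(x$converged)))
  cat("  formula:", format(x$spec), "\n")
  invisible(x)
}
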