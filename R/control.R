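#' Settings for model fitting, smoothing and inference
#'
#' @param center Mean-center continuous covariates before fitting (default
#'   `TRUE`). Binary indicators and factors are left as coded.
#' @param family Conditional distribution of the signal given covariates and
#'   random effects; only `"gaussian"` is implemented. Other families are
#'   reserved for a bootstrap confidence-band path and raise an error.
#' @param basis_size Spline basis dimension `K`; default
#'   `min(ceiling(S/2), 35)`.
#' @param lambda_grid Candidate smoothing parameters; default 100 points
#'   log-spaced in `[1e-8, 1e8]`.
#' @param selector Lambda selection rule, `"gcv"` (default) or `"fixed"`.
#' @param lambda_fixed Lambda used when `selector = "fixed"`.
#' @param level Band level (default 0.95).
#' @param draws Monte-Carlo draws for the joint critical value (default
#'   10000; quantile SE about 0.01 at that size).
#' @param seed Seed for the joint critical-value draws (default 1).
#' @param smooth_blups Smooth random-effect (BLUP) curves for display
#'   (default `TRUE`); no uncertainty is attached to BLUP curves.
#' @return A list of class `flmm_control`.
#' @export
flmm_control <- function(center = TRUE,
                         family = "gaussian",
                         basis_size = NULL,
                         lambda_grid = NULL,
                         selector = c("gcv", "fixed"),
                         lambda_fixed = NULL,
                         level = 0.95,
                         draws = 10000L,
                         seed = 1L,
                         smooth_blups = TRUE) {
  selector <- match.arg(selector)
  structure(list(center = center, family = family, basis_size = basis_size,
                 lambda_grid = lambda_grid, selector = selector,
                 lambda_fixed = lambda_fixed, level = level,
                 draws = as.integer(draws), seed = as.integer(seed),
                 smooth_blups = smooth_blups),
            class = "flmm_control")
}
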