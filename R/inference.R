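#' Method-of-moments cross-time covariance of the random effects
#'
#' For every pair of time-points `(s1, s2)` the cross-covariance `G_b(s1, s2)`
#' of each random-effect block is estimated by least-squares matching of the
#' model-implied expectation of the cross-products of marginal pointwise
#' residuals `e(s) = Y(s) - X beta_hat(s)` to their empirical values: within
#' each subject, `E[e(s1) e(s2)'] = sum_b Z_b G_b(s1, s2) Z_b' + r(s1, s2) I`
#' for `s1 != s2`, where `r(s1, s2)` is the trial-level residual cross-time
#' covariance (diagonal in the trial index), fitted jointly with the `G_b` in
#' the least squares. Diagonal blocks `G_b(s, s)` and `r(s, s)` are taken from
#' the pointwise REML variance components.
#'
#' Because the residuals are projections `e(s) = (I - X M(s)) Y(s)`, the
#' naive moment equations are deflated by the fixed-effect estimation terms
#' (an `O(1/n_subjects)` effect); by default the correction, which is linear
#' in the unknown covariances, is added back by two plug-in iterations.
#'
#' The estimated cross-covariance surfaces are then smoothed over the
#' `(s1, s2)` plane (their diagonals, the REML variance components, are kept
#' as estimated): the true surfaces are smooth, and pooling across pairs
#' removes moment-estimation noise that would otherwise propagate into the
#' band widths and fatten the tail of the max statistic.
#'
#' @param fit A [fit_pointwise()] object.
#' @param debias Apply the projection bias correction (default `TRUE`).
#' @param smooth_surfaces Smooth the estimated cross-covariance surfaces over
#'   the time-pair plane (default `TRUE`).
#' @return A list with one `q_b x q_b x S x S` array per random block (`G`),
#'   the `S x S` residual cross-covariance `R`, the converged index, and the
#'   GLS maps reused by [covariance_beta()].
#' @export
estimate_G_cross <- function(fit, debias = TRUE, smooth_surfaces = TRUE) {
  stopifnot(inherits(fit, "flmm_pointwise"))
  idx <- which(fit$converged)
  S <- length(fit$converged)
  blocks <- fit$design$blocks
  nb <- length(blocks)
  subj <- droplevels(fit$subject)
  subj_rows <- split(seq_along(subj), subj)
  n_subj <- length(subj_rows)
  X <- fit$design$X
  p <- ncol(X)

  E <- fit$Y - X %*% fit$beta_hat  # N x S marginal residuals

  # per block: level row indices and q x S matrix of Z'e per level
  blk <- lapply(blocks, function(b) {
    q <- ncol(b$Z)
    lv <- levels(droplevels(b$group))
    rows <- split(seq_along(b$group), droplevels(b$group))
    U <- array(0, c(q, S, length(lv)))
    for (gi in seq_along(lv)) {
      r <- rows[[gi]]
      U[, , gi] <- crossprod(b$Z[r, , drop = FALSE], E[r, , drop = FALSE])
    }
    list(q = q, levels = lv, rows = rows, U = U,
         level_subject = vapply(rows, function(r) as.character(subj[r[1]]),
                                character(1)))
  })

  # flat level table across blocks, with per-level projected designs
  lev <- do.call(rbind, lapply(seq_len(nb), function(bi) {
    data.frame(block = bi, gi = seq_along(blk[[bi]]$rows),
               subject = blk[[bi]]$level_subject)
  }))
  nlev <- nrow(lev)
  lev_rows <- lapply(seq_len(nlev), function(li) {
    blk[[lev$block[li]]]$rows[[lev$gi[li]]]
  })
  XtZ <- lapply(seq_len(nlev), function(li) {
    r <- lev_rows[[li]]
    crossprod(X[r, , drop = FALSE],
              blocks[[lev$block[li]]]$Z[r, , drop = FALSE])
  })
  # within-subject cross-products Z_h' Z_g over shared rows
  lev_by_subj <- split(seq_len(nlev), lev$subject)
  Cpair <- vector("list", nlev)
  for (li in seq_len(nlev)) Cpair[[li]] <- vector("list", nlev)
  for (ls in lev_by_subj) {
    for (h in ls) {
      for (g in ls) {
        shared <- intersect(lev_rows[[h]], lev_rows[[g]])
        if (!length(shared)) next
        Cpair[[h]][[g]] <-
          crossprod(blocks[[lev$block[h]]]$Z[shared, , drop = FALSE],
                    blocks[[lev$block[g]]]$Z[shared, , drop = FALSE])
      }
    }
  }
  XtX_i <- lapply(subj_rows, function(r) crossprod(X[r, , drop = FALSE]))

  # Gram of the least-squares system over [vec(G_1); ...; vec(G_nb); r], using
  # (Zg (x) Zg)' (Zh (x) Zh) = (Zg'Zh) (x) (Zg'Zh), (Zg (x) Zg)' vec(I) = vec(Zg'Zg)
  sizes <- vapply(blk, function(b) as.integer(b$q^2), integer(1))
  off <- c(0, cumsum(sizes))
  P <- sum(sizes) + 1L
  Gram <- matrix(0, P, P)
  for (h in seq_len(nlev)) {
    for (g in seq_len(nlev)) {
      C <- Cpair[[h]][[g]]
      if (is.null(C)) next
      a <- lev$block[h]
      b2 <- lev$block[g]
      ia <- (off[a] + 1):off[a + 1]
      ib <- (off[b2] + 1):off[b2 + 1]
      Gram[ia, ib] <- Gram[ia, ib] + kronecker(C, C)
    }
  }
  for (li in seq_len(nlev)) {
    a <- lev$block[li]
    ia <- (off[a] + 1):off[a + 1]
    ZtZ <- as.vector(Cpair[[li]][[li]])
    Gram[ia, P] <- Gram[ia, P] + ZtZ
    Gram[P, ia] <- Gram[P, ia] + ZtZ
  }
  Gram[P, P] <- length(subj)
  ridge <- 1e-10 * mean(diag(Gram)) * diag(nrow(Gram))
  Gram_inv <- solve(Gram + ridge)

  maps <- if (debias) gls_maps(fit, idx) else NULL

  G_cross <- lapply(blk, function(b) array(NA_real_, c(b$q, b$q, S, S)))
  R_cross <- matrix(NA_real_, S, S)
  for (bi in seq_len(nb)) {
    for (s in idx) G_cross[[bi]][, , s, s] <- fit$G_hat[[bi]][, , s]
  }
  for (s in idx) R_cross[s, s] <- fit$sigma2[s]

  n_idx <- length(idx)
  if (n_idx >= 2 && debias) {
    # Bias correction: residuals are projections e(s) = (I - X M(s)) Y(s), so
    # E[e(s1) e(s2)'] understates the cross-covariance by the fixed-effect
    # estimation terms. The correction to the least-squares right-hand side is
    # linear in theta = [vec(G_1); ...; r]; assemble it as a per-pair P x P
    # operator K from per-time-point pieces and solve the corrected system by
    # two plug-in iterations.
    p2 <- p^2
    # commutation matrices vec(G') = Tq vec(G), one per block
    Tq <- lapply(blk, function(b) {
      q <- b$q
      m <- matrix(0, q^2, q^2)
      for (u in seq_len(q)) for (v in seq_len(q)) {
        m[(u - 1) * q + v, (v - 1) * q + u] <- 1
      }
      m
    })
    # global projection-to-target map: rows per block = sum_g t(XtZ_g (x) XtZ_g),
    # last row = vec(X'X)' for the residual trace
    Tmat <- matrix(0, P, p2)
    for (li in seq_len(nlev)) {
      b <- lev$block[li]
      ib <- (off[b] + 1):off[b + 1]
      Tmat[ib, ] <- Tmat[ib, ] + t(kronecker(XtZ[[li]], XtZ[[li]]))
    }
    Tmat[P, ] <- as.vector(Reduce(`+`, XtX_i))

    # per-time-point correction operators for the two projection sides
    K1 <- vector("list", n_idx)
    K2 <- vector("list", n_idx)
    for (a in seq_len(n_idx)) {
      k1 <- matrix(0, P, P)
      k2 <- matrix(0, P, P)
      Qa <- lapply(seq_len(nlev), function(li) {
        matrix(maps$Q[[lev$block[li]]][, , lev$gi[li], a], p)
      })
      for (g in seq_len(nlev)) {
        bg <- lev$block[g]
        ig <- (off[bg] + 1):off[bg + 1]
        for (h in lev_by_subj[[lev$subject[g]]]) {
          C_hg <- Cpair[[h]][[g]]
          if (is.null(C_hg)) next
          bh <- lev$block[h]
          ih <- (off[bh] + 1):off[bh + 1]
          P_gh <- crossprod(XtZ[[g]], Qa[[h]])      # t(XtZ_g) Q_h, qg x qh
          k1[ig, ih] <- k1[ig, ih] + kronecker(t(C_hg), P_gh)
          k2[ig, ih] <- k2[ig, ih] +
            kronecker(P_gh, t(C_hg)) %*% Tq[[bh]]
        }
        P_gg <- crossprod(XtZ[[g]], Qa[[g]])
        k1[ig, P] <- k1[ig, P] + as.vector(P_gg)
        k2[ig, P] <- k2[ig, P] + as.vector(t(P_gg))
        k1[P, ig] <- k1[P, ig] + as.vector(crossprod(Qa[[g]], XtZ[[g]]))
        k2[P, ig] <- k2[P, ig] + as.vector(crossprod(XtZ[[g]], Qa[[g]]))
      }
      k1[P, P] <- p
      k2[P, P] <- p
      K1[[a]] <- k1
      K2[[a]] <- k2
    }

    Wflat <- do.call(cbind, maps$W)                  # N x (p S_c)
    vecG_pos <- lapply(seq_len(nb), function(bi) {
      q <- blk[[bi]]$q
      cbind(u = rep(seq_len(q), q), v = rep(seq_len(q), each = q))
    })

    for (ai in 1:(n_idx - 1)) {
      s1 <- idx[ai]
      U1 <- lapply(blk, function(b) matrix(b$U[, s1, ], b$q))
      e1 <- E[, s1]
      A1 <- maps$A[[ai]]
      CWall <- crossprod(maps$W[[ai]], Wflat)        # p x (p S_c)
      Q1flat <- lapply(seq_len(nb), function(bi) {   # (p q) x L, columns vec(Q_g)
        q <- blk[[bi]]$q
        L <- dim(maps$Q[[bi]])[3]
        matrix(maps$Q[[bi]][, , , ai], p * q, L)
      })
      for (bj in (ai + 1):n_idx) {
        s2 <- idx[bj]
        rhs <- c(
          unlist(lapply(seq_len(nb), function(bi) {
            U2 <- matrix(blk[[bi]]$U[, s2, ], blk[[bi]]$q)
            as.vector(U1[[bi]] %*% t(U2))
          })),
          sum(e1 * E[, s2])
        )
        theta0 <- drop(Gram_inv %*% rhs)

        A2 <- maps$A[[bj]]
        D12 <- A1 %*% CWall[, ((bj - 1) * p + 1):(bj * p)] %*% t(A2)
        Vab <- matrix(0, p2, P)
        for (bi in seq_len(nb)) {
          q <- blk[[bi]]$q
          L <- dim(maps$Q[[bi]])[3]
          big <- Q1flat[[bi]] %*% t(matrix(maps$Q[[bi]][, , , bj], p * q, L))
          pos <- vecG_pos[[bi]]
          for (e in seq_len(q^2)) {
            u <- pos[e, "u"]
            v <- pos[e, "v"]
            Vab[, off[bi] + e] <-
              as.vector(big[((u - 1) * p + 1):(u * p),
                            ((v - 1) * p + 1):(v * p)])
          }
        }
        Vab[, P] <- as.vector(D12)
        K <- K1[[ai]] + K2[[bj]] - Tmat %*% Vab
        GK <- Gram_inv %*% K
        theta <- theta0 + GK %*% (theta0 + GK %*% theta0)

        for (bi in seq_len(nb)) {
          Gb <- matrix(theta[(off[bi] + 1):off[bi + 1]], blk[[bi]]$q)
          G_cross[[bi]][, , s1, s2] <- Gb
          G_cross[[bi]][, , s2, s1] <- t(Gb)
        }
        R_cross[s1, s2] <- R_cross[s2, s1] <- theta[P]
      }
    }
  } else if (n_idx >= 2) {
    for (ai in 1:(n_idx - 1)) {
      s1 <- idx[ai]
      U1 <- lapply(blk, function(b) matrix(b$U[, s1, ], b$q))
      e1 <- E[, s1]
      for (bj in (ai + 1):n_idx) {
        s2 <- idx[bj]
        rhs <- c(
          unlist(lapply(seq_len(nb), function(bi) {
            U2 <- matrix(blk[[bi]]$U[, s2, ], blk[[bi]]$q)
            as.vector(U1[[bi]] %*% t(U2))
          })),
          sum(e1 * E[, s2])
        )
        theta <- drop(Gram_inv %*% rhs)
        for (bi in seq_len(nb)) {
          Gb <- matrix(theta[(off[bi] + 1):off[bi + 1]], blk[[bi]]$q)
          G_cross[[bi]][, , s1, s2] <- Gb
          G_cross[[bi]][, , s2, s1] <- t(Gb)
        }
        R_cross[s1, s2] <- R_cross[s2, s1] <- theta[P]
      }
    }
  }
  if (smooth_surfaces && length(idx) >= 10) {
    basis_s <- make_basis(S)
    dr_s <- basis_dr(basis_s, idx)
    # enough effective df to track the near-diagonal ridge of temporally
    # correlated trial noise while pooling away moment-estimation noise
    target <- max(5, min(ceiling(length(idx) / 3), 20))
    if (target < basis_s$K) {
      la_s <- exp(uniroot(function(l) sum(1 / (1 + exp(l) * dr_s$d)) - target,
                          c(-25, 30))$root)
      Ms <- dr_s$Bc %*% dr_s$T
      Hs <- Ms %*% ((1 / (1 + la_s * dr_s$d)) * t(Ms))
      smooth_surface <- function(Fmat) {
        sub <- Fmat[idx, idx]
        d0 <- diag(sub)
        sm <- Hs %*% sub %*% t(Hs)
        diag(sm) <- d0
        Fmat[idx, idx] <- sm
        Fmat
      }
      Rs <- smooth_surface(R_cross)
      R_cross <- (Rs + t(Rs)) / 2
      for (bi in seq_len(nb)) {
        q <- blk[[bi]]$q
        for (u in seq_len(q)) {
          for (v in u:q) {
            Fs <- smooth_surface(matrix(G_cross[[bi]][u, v, , ], S))
            if (u == v) Fs <- (Fs + t(Fs)) / 2
            G_cross[[bi]][u, v, , ] <- Fs
            G_cross[[bi]][v, u, , ] <- t(Fs)
          }
        }
      }
    }
  }
  names(G_cross) <- vapply(blocks, `[[`, character(1), "grouping")
  list(G = G_cross, R = R_cross, idx = idx, maps = maps)
}

blk_q_of <- function(blk, bi) blk[[bi]]$q

# per-time-point GLS pieces shared by the moment estimator and the covariance
# assembly: A(s) = (X'V^-1 X)^-1, W(s) = V^-1 X (N x p, V block diagonal by
# subject) and Q_g(s) = M(s) Z_g per random-effect level
gls_maps <- function(fit, idx = which(fit$converged), G_diag = NULL) {
  if (is.null(G_diag)) G_diag <- fit$G_hat
  blocks <- fit$design$blocks
  nb <- length(blocks)
  X <- fit$design$X
  p <- ncol(X)
  N <- nrow(X)
  subj <- droplevels(fit$subject)
  subj_rows <- split(seq_along(subj), subj)
  n_subj <- length(subj_rows)
  S_c <- length(idx)

  blk <- lapply(blocks, function(b) {
    list(q = ncol(b$Z),
         rows = split(seq_along(b$group), droplevels(b$group)))
  })
  A_list <- vector("list", S_c)
  W_list <- vector("list", S_c)
  Q_list <- lapply(seq_len(nb), function(bi) {
    array(0, c(p, blk[[bi]]$q, length(blk[[bi]]$rows), S_c))
  })
  for (a in seq_len(S_c)) {
    s <- idx[a]
    sig2 <- fit$sigma2[s]
    Wmat <- matrix(0, N, p)
    XtVX <- matrix(0, p, p)
    for (i in seq_len(n_subj)) {
      r <- subj_rows[[i]]
      Vi <- diag(sig2, length(r))
      for (bi in seq_len(nb)) {
        Gss <- matrix(G_diag[[bi]][, , s], blk[[bi]]$q)
        for (gi in seq_along(blk[[bi]]$rows)) {
          rg <- blk[[bi]]$rows[[gi]]
          loc <- match(rg, r)
          if (anyNA(loc)) { loc <- loc[!is.na(loc)]; rg <- r[loc] }
          if (!length(loc)) next
          Zg <- blocks[[bi]]$Z[rg, , drop = FALSE]
          Vi[loc, loc] <- Vi[loc, loc] + Zg %*% Gss %*% t(Zg)
        }
      }
      Wi <- solve(Vi, X[r, , drop = FALSE])
      Wmat[r, ] <- Wi
      XtVX <- XtVX + crossprod(X[r, , drop = FALSE], Wi)
    }
    A <- solve(XtVX)
    A_list[[a]] <- A
    W_list[[a]] <- Wmat
    for (bi in seq_len(nb)) {
      for (gi in seq_along(blk[[bi]]$rows)) {
        rg <- blk[[bi]]$rows[[gi]]
        Q_list[[bi]][, , gi, a] <-
          A %*% crossprod(Wmat[rg, , drop = FALSE],
                          blocks[[bi]]$Z[rg, , drop = FALSE])
      }
    }
  }
  list(A = A_list, W = W_list, Q = Q_list, idx = idx)
}

#' Covariance of the smoothed coefficient functions
#'
#' Assembles, for each coefficient function `k`, the S x S covariance of the
#' smoothed estimator `beta_tilde_k = H_k beta_hat_k`. The raw cross-time
#' covariance is `Cov(beta_hat(s1), beta_hat(s2)) = M(s1) Sigma(s1,s2) M(s2)'`
#' with `M(s)` the per-time-point GLS coefficient map
#' `(X'V(s)^-1 X)^-1 X'V(s)^-1` and
#' `Sigma(s1,s2) = Z G(s1,s2) Z' + r(s1,s2) I`, where the residual
#' cross-covariance `r` is diagonal in the trial index (estimated by the same
#' moment matching; `r(s,s)` is the REML residual variance). The diagonal
#' `Cov(beta_hat(s), beta_hat(s))` equals the pointwise REML Wald covariance.
#' The smoothed covariance `H_k Cov_k H_k'` is symmetrized and
#' eigenvalue-clipped at zero.
#'
#' @param fit A [fit_pointwise()] object (Gaussian family).
#' @param smoother A [smooth_coefficients()] result.
#' @param G_cross Optional [estimate_G_cross()] result (estimated if absent);
#'   supplying a known cross-covariance supports oracle checks.
#' @return A list per coefficient of S x S positive semidefinite covariance
#'   matrices of the smoothed coefficient function.
#' @export
covariance_beta <- function(fit, smoother, G_cross = NULL) {
  stopifnot(inherits(fit, "flmm_pointwise"))
  if (!identical(fit$control$family, "gaussian")) {
    abort("covariance_beta: bootstrap path for non-gaussian families not implemented")
  }
  if (is.null(G_cross)) G_cross <- estimate_G_cross(fit)
  idx <- G_cross$idx
  S_c <- length(idx)
  blocks <- fit$design$blocks
  nb <- length(blocks)
  p <- ncol(fit$design$X)

  maps <- G_cross$maps
  if (is.null(maps) || !identical(maps$idx, idx)) {
    # e.g. a user-supplied (known) cross-covariance: build the GLS maps from
    # its diagonal so the assembly is consistent with the given components
    G_diag <- lapply(seq_len(nb), function(bi) {
      q <- dim(G_cross$G[[bi]])[1]
      arr <- array(NA_real_, c(q, q, length(fit$converged)))
      for (s in idx) arr[, , s] <- G_cross$G[[bi]][, , s, s]
      arr
    })
    maps <- gls_maps(fit, idx, G_diag = G_diag)
  }
  blk_L <- vapply(seq_len(nb), function(bi) dim(maps$Q[[bi]])[3], integer(1))
  blk_q <- vapply(seq_len(nb), function(bi) dim(maps$Q[[bi]])[2], integer(1))

  # raw covariance entries for every coefficient
  cov_raw <- lapply(seq_len(p), function(k) matrix(0, S_c, S_c))
  for (a in seq_len(S_c)) {
    Vd <- fit$vcov[, , idx[a]]
    for (k in seq_len(p)) cov_raw[[k]][a, a] <- Vd[k, k]
  }
  R_cross <- G_cross$R
  if (S_c >= 2) {
    for (a in 1:(S_c - 1)) {
      for (b2 in (a + 1):S_c) {
        Cab <- matrix(0, p, p)
        for (bi in seq_len(nb)) {
          q <- blk_q[bi]
          L <- blk_L[bi]
          G12 <- matrix(G_cross$G[[bi]][, , idx[a], idx[b2]], q)
          Q1 <- matrix(maps$Q[[bi]][, , , a], p, q * L)
          Q2 <- matrix(maps$Q[[bi]][, , , b2], p, q * L)
          T2 <- matrix(as.vector(t(Q2)), nrow = q)      # q x (L p)
          K <- matrix(as.vector(G12 %*% T2), nrow = q * L)
          Cab <- Cab + Q1 %*% K
        }
        r12 <- if (is.null(R_cross)) 0 else R_cross[idx[a], idx[b2]]
        if (is.finite(r12) && r12 != 0) {
          Cab <- Cab + r12 * (maps$A[[a]] %*%
                                crossprod(maps$W[[a]], maps$W[[b2]]) %*%
                                t(maps$A[[b2]]))
        }
        for (k in seq_len(p)) {
          cov_raw[[k]][a, b2] <- Cab[k, k]
          cov_raw[[k]][b2, a] <- Cab[k, k]
        }
      }
    }
  }

  lapply(seq_len(p), function(k) {
    Hk <- smoother$H[[k]]
    C <- Hk %*% cov_raw[[k]] %*% t(Hk)
    psd_clip((C + t(C)) / 2)
  })
}

# eigenvalue-clip a symmetric matrix at zero
psd_clip <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  if (all(eg$values >= 0)) return(C)
  v <- pmax(eg$values, 0)
  C2 <- eg$vectors %*% (v * t(eg$vectors))
  (C2 + t(C2)) / 2
}

#' Simulation-based critical value for a simultaneous confidence band
#'
#' Draws mean-zero Gaussian vectors with the given correlation and returns the
#' `level` empirical quantile of `max_s |xi(s)|`. The result is floored at the
#' pointwise normal quantile so the joint band is never narrower than the
#' pointwise band. Deterministic given `seed`.
#'
#' @param correlation S x S correlation matrix (PSD after repair, unit
#'   diagonal).
#' @param level Band level (default 0.95).
#' @param draws Monte-Carlo draws (default 10000); fewer than 1000 triggers a
#'   quantile-instability warning.
#' @param seed Integer seed.
#' @return The critical multiplier `q >= qnorm((1+level)/2)`.
#' @export
joint_critical_value <- function(correlation, level = 0.95, draws = 10000L,
                                 seed = 1L) {
  correlation <- as.matrix(correlation)
  S <- nrow(correlation)
  if (draws < 1000L) {
    warn("joint_critical_value: fewer than 1000 draws; quantile is unstable")
  }
  eg <- eigen((correlation + t(correlation)) / 2, symmetric = TRUE)
  Lhalf <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), S)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  Z <- matrix(rnorm(S * draws), S, draws)
  A <- abs(Lhalf %*% Z)
  # column maxima without per-column apply overhead
  maxabs <- do.call(pmax.int, lapply(seq_len(S), function(i) A[i, ]))
  unname(max(quantile(maxabs, level, type = 7), qnorm((1 + level) / 2)))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Fit a functional linear mixed model with pointwise and joint bands
#'
#' The full estimation pipeline: a Gaussian linear mixed model is fit at every
#' trial time-point by REML ([fit_pointwise()]); each raw coefficient function
#' is smoothed with a penalized B-spline smoother ([smooth_coefficients()]);
#' the covariance of the smoothed coefficient functions is assembled
#' analytically with a method-of-moments estimate of the cross-time
#' random-effect covariance ([covariance_beta()]); and simultaneous 95%
#' bands are built from the max of a correlated Gaussian vector
#' ([joint_critical_value()]).
#'
#' @param data An [fd_data()] object.
#' @param formula A mixed-model formula string or formula, e.g.
#'   `"photometry ~ delay + (delay | id)"`; nested grouping `id/session` is
#'   supported.
#' @param control A [flmm_control()] list.
#' @return An object of class `flmm_fit`; see [tidy.flmm_fit()],
#'   [glance.flmm_fit()] and [autoplot.flmm_fit()].
#' @export
#' @examples
#' truth <- default_truth(S = 24)
#' cfg <- sim_config(n_subjects = 4, trials_per_condition = 8, S = 24, seed = 2)
#' sim <- simulate_dataset(cfg)
#' fit <- fit_flmm(sim$data, "y ~ x + (x | id)")
#' glance(fit)
fit_flmm <- function(data, formula, control = flmm_control()) {
  spec <- with_stage("formula", {
    if (inherits(formula, "flmm_formula")) formula else parse_formula(formula)
  })
  fit <- with_stage("pointwise", fit_pointwise(data, spec, control))
  smoother <- with_stage("smoothing", smooth_coefficients(fit, control))
  res <- with_stage("inference", {
    cov_beta <- covariance_beta(fit, smoother)
    assemble_bands(fit, smoother, cov_beta, control)
  })
  res
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

assemble_bands <- function(fit, smoother, cov_beta, control) {
  p <- nrow(fit$beta_hat)
  S <- ncol(fit$beta_hat)
  terms <- rownames(fit$beta_hat)
  level <- control$level

  se <- matrix(NA_real_, p, S, dimnames = list(terms, NULL))
  q_crit <- setNames(numeric(p), terms)
  for (k in seq_len(p)) {
    dk <- pmax(diag(cov_beta[[k]]), 0)
    se[k, ] <- sqrt(dk)
    corr <- cov_beta[[k]]
    d <- sqrt(dk)
    pos <- d > 0
    corr <- corr / (d %o% d)
    corr[!pos, ] <- 0
    corr[, !pos] <- 0
    diag(corr) <- 1
    q_crit[k] <- joint_critical_value(corr, level = level,
                                      draws = control$draws,
                                      seed = control$seed)
  }

  blups_smooth <- fit$blups
  if (isTRUE(control$smooth_blups) && !smoother$identity) {
    basis <- smoother$basis
    idx <- which(smoother$converged)
    dr <- basis_dr(basis, idx)
    grid <- control$lambda_grid %||% default_lambda_grid()
    blups_smooth <- lapply(fit$blups, function(arr) {
      out <- arr
      for (l in seq_len(dim(arr)[1])) {
        for (j in seq_len(dim(arr)[2])) {
          y <- arr[l, j, idx]
          if (all(is.finite(y))) {
            la <- pick_lambda(dr, y, grid)
            out[l, j, ] <- drop(basis$B %*% dr_coef(dr, y, la))
          }
        }
      }
      out
    })
  }

  ic <- information_criteria(fit)
  structure(list(
    terms = terms,
    time_grid = fit$time_grid,
    beta_tilde = smoother$beta_tilde,
    beta_hat = fit$beta_hat,
    se_pointwise = se,
    se_joint_halfwidth = q_crit * se,
    q_crit = q_crit,
    cov_beta = setNames(cov_beta, terms),
    blups = blups_smooth,
    blups_raw = fit$blups,
    aic = ic$aic, bic = ic$bic,
    level = level,
    diagnostics = tibble::tibble(s = seq_len(S), time = fit$time_grid,
                                 converged = fit$converged),
    smoother = smoother,
    pointwise = fit,
    spec = fit$spec,
    control = control
  ), class = "flmm_fit")
}

#' @export
print.flmm_fit <- function(x, ...) {
  cat("<flmm_fit> functional linear mixed model\n")
  cat("  formula:", format(x$spec), "\n")
  cat(sprintf("  %d coefficient function(s) on %d time-points; %d/%d converged\n",
              length(x$terms), length(x$time_grid),
              sum(x$diagnostics$converged), nrow(x$diagnostics)))
  cat(sprintf("  joint critical values: %s (pointwise %.3f)\n",
              paste(sprintf("%s=%.3f", x$terms, x$q_crit), collapse = ", "),
              qnorm((1 + x$level) / 2)))
  cat(sprintf("  AIC %.1f, BIC %.1f (summed REML criteria)\n", x$aic, x$bic))
  invisible(x)
}

#' Tidy per-time-point estimates and bands of a fitted model
#'
#' @param x An [fit_flmm()] result.
#' @param ... Unused.
#' @return A tibble with one row per (term, time-point): `estimate`, `se`,
#'   `pointwise_lo/hi`, `joint_lo/hi`.
#' @method tidy flmm_fit
#' @export
tidy.flmm_fit <- function(x, ...) {
  z <- qnorm((1 + x$level) / 2)
  purrr::map_dfr(seq_along(x$terms), function(k) {
    tibble::tibble(
      term = x$terms[k],
      s = seq_along(x$time_grid),
      time = x$time_grid,
      estimate = x$beta_tilde[k, ],
      se = x$se_pointwise[k, ],
      pointwise_lo = x$beta_tilde[k, ] - z * x$se_pointwise[k, ],
      pointwise_hi = x$beta_tilde[k, ] + z * x$se_pointwise[k, ],
      joint_lo = x$beta_tilde[k, ] - x$se_joint_halfwidth[k, ],
      joint_hi = x$beta_tilde[k, ] + x$se_joint_halfwidth[k, ]
    )
  })
}

#' One-row model summary
#'
#' @param x An [fit_flmm()] result.
#' @param ... Unused.
#' @return A tibble with `aic`, `bic`, `n_trials`, `n_timepoints`,
#'   `n_converged` and the per-term joint critical values collapsed to their
#'   range.
#' @method glance flmm_fit
#' @export
glance.flmm_fit <- function(x, ...) {
  tibble::tibble(
    aic = x$aic, bic = x$bic,
    n_trials = nrow(x$pointwise$Y),
    n_timepoints = length(x$time_grid),
    n_converged = sum(x$diagnostics$converged),
    q_crit_min = min(x$q_crit), q_crit_max = max(x$q_crit)
  )
}

#' Coefficient-function plot with pointwise and joint bands
#'
#' One panel per coefficient function: the smoothed estimate with a dark
#' (pointwise) and light (joint) 95% band, and a zero reference line.
#'
#' @param object An [fit_flmm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flmm_fit
#' @export
autoplot.flmm_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$joint_lo,
                                      ymax = .data$joint_hi),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pointwise_lo,
                                      ymax = .data$pointwise_hi),
                         fill = "grey55") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "trial time (s)", y = "coefficient",
                  title = "Functional coefficient estimates",
                  subtitle = "dark band: pointwise 95% CI; light band: joint 95% CI") +
    ggplot2::theme_minimal()
}
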