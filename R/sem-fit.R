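# --- model-implied moments and derivatives -------------------------------

# precomputed integer index plan so the hot path is pure array indexing
sem_plan <- function(spec) {
  Tt <- length(spec$traits); K <- length(spec$factors)
  lo_r <- match(spec$loadings$trait, spec$traits)
  lo_c <- match(spec$loadings$factor, spec$factors)
  lo_free <- spec$loadings$free
  lo_val <- spec$loadings$value
  psi_pairs <- NULL
  if (K > 1) {
    low <- which(lower.tri(diag(K)), arr.ind = TRUE)
    keep <- spec$psi_free[low]
    psi_pairs <- low[keep, , drop = FALSE]
  }
  idx <- vech_index(Tt)
  # theta layout: free loadings, free psi covariances, free residuals
  n_lo <- sum(lo_free)
  n_ps <- if (is.null(psi_pairs)) 0L else nrow(psi_pairs)
  list(Tt = Tt, K = K, q = spec$q,
       lo_r = lo_r, lo_c = lo_c, lo_free = lo_free, lo_val = lo_val,
       psi_pairs = psi_pairs,
       resid_free = spec$resid$free, resid_val = spec$resid$value,
       pos_lo = seq_len(n_lo),
       pos_ps = if (n_ps) n_lo + seq_len(n_ps) else integer(0),
       pos_re = n_lo + n_ps + seq_len(sum(spec$resid$free)),
       vi = idx$row, vj = idx$col,
       traits = spec$traits, factors = spec$factors)
}

sem_matrices_plan <- function(plan, theta) {
  Lambda <- matrix(0, plan$Tt, plan$K)
  vals <- plan$lo_val
  vals[plan$lo_free] <- theta[plan$pos_lo]
  Lambda[cbind(plan$lo_r, plan$lo_c)] <- vals
  Psi <- diag(1, plan$K)
  if (length(plan$pos_ps)) {
    Psi[plan$psi_pairs] <- theta[plan$pos_ps]
    Psi[plan$psi_pairs[, 2:1, drop = FALSE]] <- theta[plan$pos_ps]
  }
  th <- plan$resid_val
  th[plan$resid_free] <- theta[plan$pos_re]
  list(Lambda = Lambda, Psi = Psi, Theta = th)
}

sem_matrices <- function(spec, theta) {
  m <- sem_matrices_plan(sem_plan(spec), theta)
  dimnames(m$Lambda) <- list(spec$traits, spec$factors)
  dimnames(m$Psi) <- list(spec$factors, spec$factors)
  names(m$Theta) <- spec$traits
  m
}

sem_implied_plan <- function(plan, theta) {
  m <- sem_matrices_plan(plan, theta)
  Sg <- m$Lambda %*% tcrossprod(m$Psi, m$Lambda)
  diag(Sg) <- diag(Sg) + m$Theta
  Sg[cbind(plan$vi, plan$vj)]
}

sem_implied_matrix <- function(spec, theta) {
  m <- sem_matrices(spec, theta)
  m$Lambda %*% m$Psi %*% t(m$Lambda) + diag(m$Theta, length(m$Theta))
}

sem_implied <- function(spec, theta) sem_implied_plan(sem_plan(spec), theta)

# analytic Jacobian d vech(Sigma) / d theta, t* x q
sem_jacobian_plan <- function(plan, theta) {
  m <- sem_matrices_plan(plan, theta)
  vi <- plan$vi; vj <- plan$vj
  LP <- m$Lambda %*% m$Psi
  J <- matrix(0, length(vi), plan$q)
  free_idx <- which(plan$lo_free)
  for (p in seq_along(free_idx)) {
    i <- free_idx[p]
    t_ <- plan$lo_r[i]; k_ <- plan$lo_c[i]
    g <- LP[, k_]
    J[, plan$pos_lo[p]] <- (vi == t_) * g[vj] + (vj == t_) * g[vi]
  }
  if (length(plan$pos_ps)) {
    for (p in seq_along(plan$pos_ps)) {
      k_ <- plan$psi_pairs[p, 1]; l_ <- plan$psi_pairs[p, 2]
      J[, plan$pos_ps[p]] <- m$Lambda[vi, k_] * m$Lambda[vj, l_] +
                             m$Lambda[vi, l_] * m$Lambda[vj, k_]
    }
  }
  free_re <- which(plan$resid_free)
  for (p in seq_along(free_re)) {
    J[, plan$pos_re[p]] <- as.numeric(vi == free_re[p] & vj == free_re[p])
  }
  J
}

sem_jacobian <- function(spec, theta) sem_jacobian_plan(sem_plan(spec), theta)

# exact residual-curvature term sum_c w_c r_c d2sigma_c/dtheta2 (q x q).
# Only loading x loading and loading x psi second derivatives are nonzero.
sem_hess_correction <- function(plan, theta, wr) {
  m <- sem_matrices_plan(plan, theta)
  Tt <- plan$Tt
  Mwr <- matrix(0, Tt, Tt)
  Mwr[cbind(plan$vi, plan$vj)] <- wr
  Mwr[cbind(plan$vj, plan$vi)] <- wr
  C <- matrix(0, plan$q, plan$q)
  free_lo <- which(plan$lo_free)
  lr <- plan$lo_r[free_lo]; lc <- plan$lo_c[free_lo]
  if (length(free_lo)) {
    C[plan$pos_lo, plan$pos_lo] <-
      Mwr[lr, lr, drop = FALSE] * m$Psi[lc, lc, drop = FALSE] *
      (1 + outer(lr, lr, `==`))
  }
  if (length(plan$pos_ps) && length(free_lo)) {
    MwrL <- Mwr %*% m$Lambda            # (t, k') -> sum_j Mwr[t,j] lambda[j,k']
    dMwr <- diag(Mwr)
    for (p in seq_along(plan$pos_ps)) {
      l_ <- plan$psi_pairs[p, 1]; mm <- plan$psi_pairs[p, 2]
      col <- (lc == l_) * (MwrL[lr, mm] + dMwr[lr] * m$Lambda[lr, mm]) +
             (lc == mm) * (MwrL[lr, l_] + dMwr[lr] * m$Lambda[lr, l_])
      C[plan$pos_lo, plan$pos_ps[p]] <- col
      C[plan$pos_ps[p], plan$pos_lo] <- col
    }
  }
  C
}

# --- DWLS optimizer: Levenberg-Marquardt with analytic Jacobian ----------

dwls_optimize <- function(plan, s, w, start, gtol = 1e-8, max_iter = 200) {
  obj <- function(th) { r <- sem_implied_plan(plan, th) - s; sum(w * r^2) }
  grad <- function(th) {
    r <- sem_implied_plan(plan, th) - s
    2 * crossprod(sem_jacobian_plan(plan, th), w * r)[, 1]
  }
  # quasi-Newton phase gets close fast; Levenberg-Marquardt then polishes
  # the gradient down to gtol
  qn <- tryCatch(
    stats::nlminb(start, obj, grad,
                  control = list(iter.max = 500, eval.max = 1000,
                                 rel.tol = 1e-14, abs.tol = 0)),
    error = function(e) NULL)
  theta <- if (!is.null(qn) && is.finite(qn$objective) && qn$objective <= obj(start)) {
    qn$par
  } else start
  r <- sem_implied_plan(plan, theta) - s
  F_ <- sum(w * r^2)
  lam <- 1e-4
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    J <- sem_jacobian_plan(plan, theta)
    g <- 2 * crossprod(J, w * r)[, 1]
    gnorm <- sqrt(sum(g^2))
    if (gnorm < gtol) break
    # damped Newton: Gauss-Newton term plus exact residual curvature
    A <- crossprod(J, J * w) + sem_hess_correction(plan, theta, w * r)
    d <- pmax(abs(diag(A)), 1e-10)
    accepted <- FALSE
    for (tries in 1:60) {
      step <- tryCatch(solve(A + lam * diag(d, length(d)), crossprod(J, w * r)[, 1]),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta - step
        rc <- sem_implied_plan(plan, cand) - s
        Fc <- sum(w * rc^2)
        if (is.finite(Fc) && Fc <= F_) {
          theta <- cand; r <- rc; F_ <- Fc
          lam <- max(lam / 3, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lam <- lam * 4
      if (lam > 1e12) break
    }
    if (!accepted) break
  }
  list(theta = theta, F = F_, gnorm = gnorm, converged = gnorm < gtol, iter = it)
}

# EFA-informed start values mapped onto the spec's pattern
efa_start <- function(spec, S_corr) {
  K <- length(spec$factors)
  Tt <- length(spec$traits)
  ef <- tryCatch(efa_fit(smooth_to_psd(S_corr), k = K), error = function(e) NULL)
  pt <- param_table(spec)
  theta <- numeric(spec$q)
  L0 <- matrix(0.5, Tt, K, dimnames = list(spec$traits, spec$factors))
  Phi0 <- matrix(0.2, K, K); diag(Phi0) <- 1
  if (!is.null(ef) && K >= 1) {
    # match EFA columns to spec factors by congruence with the 0/1 pattern
    pat <- matrix(0, Tt, K, dimnames = list(spec$traits, spec$factors))
    for (i in seq_len(nrow(spec$loadings))) {
      pat[spec$loadings$trait[i], spec$loadings$factor[i]] <- 1
    }
    if (K > 1) {
      cg <- tucker_congruence(pat, ef$loadings)
      perm <- attr(cg, "permutation")
      L0 <- ef$loadings[, perm, drop = FALSE]
      Phi0 <- ef$Phi[perm, perm, drop = FALSE]
    } else L0 <- ef$loadings
  }
  dimnames(L0) <- list(spec$traits, spec$factors)
  dimnames(Phi0) <- list(spec$factors, spec$factors)
  comm <- pmin(diag(L0 %*% Phi0 %*% t(L0)), 0.95)
  for (i in seq_len(spec$q)) {
    theta[i] <- switch(pt$type[i],
      loading = L0[pt$rhs[i], pt$lhs[i]],
      psi = max(min(Phi0[pt$lhs[i], pt$rhs[i]], 0.8), -0.8),
      resid = 1 - comm[pt$lhs[i]])
  }
  theta
}

generic_start <- function(spec) {
  pt <- param_table(spec)
  ifelse(pt$type == "loading", 0.5, ifelse(pt$type == "psi", 0.2, 0.5))
}

#' Fit a confirmatory factor model by diagonally weighted least squares
#'
#' Minimizes `F(theta) = (s - sigma(theta))' diag(V)^{-1} (s - sigma(theta))`
#' over the free parameters, where `s = vech(S_corr)` and `sigma(theta)`
#' is the model-implied correlation structure `Lambda Psi Lambda' + Theta`.
#' Optimization is multi-start (an EFA-informed start, a generic start, and
#' jittered restarts under fixed seeds) Levenberg-Marquardt with an
#' analytic Jacobian; convergence requires gradient norm below `gtol`.
#' Negative residual variances are permitted and flagged.  Standard errors
#' are sandwich corrections using the full V; fit indices (chi-square, CFI,
#' SRMR, AIC) are attached.
#'
#' @param spec A `factor_model_spec` (or model text parsed against the
#'   row names of `S_corr`).
#' @param S_corr Genetic correlation matrix (T x T).
#' @param V Sampling covariance of vech(S_corr), t* x t*.
#' @param n_starts Total optimizer starts (default 5: EFA start, generic
#'   start, 3 jitters of the EFA start).
#' @param seed Seed for the jittered restarts (default 1).
#' @param start Optional explicit start vector (replaces the EFA start).
#' @param gtol Gradient-norm convergence tolerance (default 1e-8).
#' @param nonneg_resid If TRUE, residual variances are constrained to be
#'   non-negative (soft floor at 0 via reparameterization is not used;
#'   offending solutions are rejected during the multi-start).
#' @return A `gsem_fit`.
#' @export
fit_dwls <- function(spec, S_corr, V, n_starts = 5, seed = 1, start = NULL,
                     gtol = 1e-8, nonneg_resid = FALSE) {
  if (is.character(spec)) spec <- parse_model(spec, rownames(S_corr))
  S_corr <- check_symmetric(as.matrix(S_corr), "S_corr")
  Tt <- length(spec$traits)
  if (nrow(S_corr) != Tt) abort("dimension mismatch between spec and S_corr",
                                class = "transgsem_input_error")
  idx_order <- match(spec$traits, rownames(S_corr) %||% spec$traits)
  if (anyNA(idx_order)) abort("S_corr row names must cover the spec's traits",
                              class = "transgsem_input_error")
  s <- vech(S_corr[spec$traits, spec$traits])
  V <- as.matrix(V)
  if (nrow(V) != spec$tstar) abort("V must be t* x t*", class = "transgsem_input_error")
  dV <- diag(V)
  if (any(dV <= 0)) abort("diag(V) must be positive", class = "transgsem_input_error")
  w <- 1 / dV
  df <- spec$tstar - spec$q
  if (df < 0) abort("negative degrees of freedom", class = "transgsem_identification_error")

  base <- start %||% efa_start(spec, S_corr)
  starts <- list(base, generic_start(spec))
  n_jitter <- max(n_starts - length(starts), 0)
  pt <- param_table(spec)
  for (i in seq_len(n_jitter)) {
    set.seed(seed * 1000L + i)
    starts[[length(starts) + 1]] <- base + rnorm(spec$q, 0, 0.1)
  }

  resid_pos <- which(pt$type == "resid")
  plan <- sem_plan(spec)
  runs <- lapply(starts, function(st) dwls_optimize(plan, s, w, st, gtol = gtol))
  ok <- vapply(runs, function(r) r$converged, logical(1))
  if (nonneg_resid) {
    nn <- vapply(runs, function(r) all(r$theta[resid_pos] >= -1e-10), logical(1))
    if (any(ok & nn)) ok <- ok & nn
  }
  if (!any(ok)) {
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "F"))]]
    abort(sprintf(
      "DWLS did not converge after %d starts (best F = %.6g, gradient norm %.3g)",
      length(runs), best$F, best$gnorm),
      class = "transgsem_convergence_error",
      best = best)
  }
  Fs <- vapply(runs, `[[`, numeric(1), "F")
  Fs[!ok] <- Inf
  best <- runs[[which.min(Fs)]]
  theta <- best$theta
  if (nonneg_resid) theta[resid_pos] <- pmax(theta[resid_pos], 0)

  implied <- sem_implied_matrix(spec, theta)
  dimnames(implied) <- list(spec$traits, spec$traits)
  mats <- sem_matrices(spec, theta)

  sw <- sandwich_cov(spec, theta, V)
  se <- sqrt(pmax(diag(sw$cov), 0))
  fi <- fit_indices_impl(s, vech(implied), V, spec$q, Tt)

  params <- pt
  params$estimate <- theta
  params$std.error <- se
  params$statistic <- theta / se
  params$p.value <- 2 * stats::pnorm(-abs(params$statistic))

  neg_resid <- pt$type == "resid" & theta < 0
  fixed_resid <- dplyr::filter(spec$resid, !.data$free)

  structure(list(spec = spec, theta = theta, params = params,
                 F_min = best$F, gnorm = best$gnorm, converged = best$converged,
                 n_starts = length(runs), n_converged = sum(ok),
                 chisq = fi$chisq, df = fi$df, cfi = fi$cfi, srmr = fi$srmr,
                 aic = fi$aic, chisq_indep = fi$chisq_indep, df_indep = fi$df_indep,
                 v_condition = fi$v_condition, v_warning = fi$v_warning,
                 implied = implied, residuals = S_corr[spec$traits, spec$traits] - implied,
                 Lambda = mats$Lambda, Psi = mats$Psi, Theta = mats$Theta,
                 vcov_theta = sw$cov, jacobian_check = sw$fd_check,
                 negative_resid = params$lhs[neg_resid],
                 s = s, V = V, w = w),
            class = "gsem_fit")
}

# sandwich covariance with finite-difference Jacobian (central, step 1e-6),
# cross-checked against forward differences
sandwich_cov <- function(spec, theta, V, step = 1e-6) {
  q <- spec$q
  tstar <- spec$tstar
  plan <- sem_plan(spec)
  Jc <- matrix(0, tstar, q)
  Jf <- matrix(0, tstar, q)
  f0 <- sem_implied_plan(plan, theta)
  for (i in seq_len(q)) {
    e <- numeric(q); e[i] <- step
    up <- sem_implied_plan(plan, theta + e)
    dn <- sem_implied_plan(plan, theta - e)
    Jc[, i] <- (up - dn) / (2 * step)
    Jf[, i] <- (up - f0) / step
  }
  fd_check <- max(abs(Jc - Jf))
  W <- 1 / diag(V)
  A <- crossprod(Jc, Jc * W)
  qrA <- qr(A)
  if (qrA$rank < q) {
    aliased <- param_table(spec)[abs(diag(qr.R(qrA))) < 1e-10, , drop = FALSE]
    abort(sprintf("rank-deficient Jacobian; aliased parameter(s): %s",
                  paste(paste(aliased$type, aliased$lhs, aliased$rhs, sep = ":"),
                        collapse = ", ")),
          class = "transgsem_identification_error")
  }
  Ai <- solve(A)
  mid <- crossprod(Jc * W, V %*% (Jc * W))
  list(cov = Ai %*% mid %*% Ai, fd_check = fd_check, jacobian = Jc)
}

#' Sandwich standard errors for a fitted model
#'
#' Recomputes the parameter covariance
#' `(D'WD)^{-1} D'W V W D (D'WD)^{-1}` with `W = diag(V)^{-1}` and the
#' Jacobian `D` by central finite differences (step 1e-6, cross-checked
#' against forward differences).
#'
#' @param fit A `gsem_fit`.
#' @param V Sampling covariance (defaults to the one used in the fit).
#' @return Tibble of free parameters and standard errors.
#' @export
sandwich_se <- function(fit, V = fit$V) {
  sw <- sandwich_cov(fit$spec, fit$theta, V)
  out <- param_table(fit$spec)
  out$std.error <- sqrt(pmax(diag(sw$cov), 0))
  out
}

fit_indices_impl <- function(s, sigma, V, q, Tt) {
  tstar <- length(s)
  df <- tstar - q
  ev <- eigen(V, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-12
  v_condition <- max(ev$values) / min(ev$values[pos])
  v_warning <- v_condition > 1e12
  if (v_warning) warn(sprintf("V pseudo-inverse condition number %.3g exceeds 1e12",
                              v_condition))
  Vp <- ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  r <- s - sigma
  chisq <- max(drop(t(r) %*% Vp %*% r), 0)
  # independence model: free diagonal, zero off-diagonals
  idx <- vech_index(Tt)
  s_indep <- ifelse(idx$row == idx$col, s, 0)
  r_i <- s - s_indep
  chisq_i <- max(drop(t(r_i) %*% Vp %*% r_i), 0)
  df_i <- tstar - Tt
  num <- max(chisq - df, 0)
  den <- max(chisq_i - df_i, chisq - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  srmr <- sqrt(mean(r^2))
  aic <- chisq + 2 * q
  list(chisq = chisq, df = df, cfi = cfi, srmr = srmr, aic = aic,
       chisq_indep = chisq_i, df_indep = df_i,
       v_condition = v_condition, v_warning = v_warning)
}

#' Fit indices for a fitted model
#'
#' Chi-square `(s - sigma)' V^+ (s - sigma)` with df = t* - q, CFI against
#' the independence model (free diagonal, zero off-diagonals), SRMR over
#' the lower triangle including the diagonal, and AIC = chi-square + 2q.
#'
#' @param fit A `gsem_fit`.
#' @param S_corr,V Optionally override the fitted target.
#' @return A one-row tibble with `chisq`, `df`, `cfi`, `srmr`, `aic`.
#' @export
fit_indices <- function(fit, S_corr = NULL, V = fit$V) {
  s <- if (is.null(S_corr)) fit$s else vech(as.matrix(S_corr)[fit$spec$traits, fit$spec$traits])
  fi <- fit_indices_impl(s, vech(fit$implied), V, fit$spec$q, length(fit$spec$traits))
  tibble(chisq = fi$chisq, df = fi$df, cfi = fi$cfi, srmr = fi$srmr, aic = fi$aic)
}

#' Compare fitted models by AIC
#'
#' All fits must target identical observed moments and sampling covariance.
#' Ties in AIC are broken by fewer free parameters.
#'
#' @param ... Named `gsem_fit` objects (or a single list of them).
#' @return Tibble sorted by AIC ascending with `delta_aic`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "gsem_fit")) fits <- fits[[1]]
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(ref$s, f$s, tolerance = 1e-12)) ||
        !isTRUE(all.equal(ref$V, f$V, tolerance = 1e-12))) {
      abort("models were fitted to different (S_corr, V) inputs",
            class = "transgsem_input_error")
    }
  }
  out <- purrr::imap(fits, function(f, nm) {
    tibble(model = nm, q = f$spec$q, chisq = f$chisq, df = f$df,
           cfi = f$cfi, srmr = f$srmr, aic = f$aic)
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$aic, .data$q)
  out$delta_aic <- out$aic - out$aic[1]
  out
}

#' Standardized solution of a fitted model
#'
#' Rescales the solution so the model-implied variances are exactly 1:
#' `Lambda* = D Lambda`, `Theta* = D^2 Theta` with
#' `D = diag(implied)^{-1/2}`.  When residual variances are free the
#' implied diagonal already equals 1 at the optimum and this is the
#' identity.
#'
#' @param fit A `gsem_fit`.
#' @return List with `Lambda`, `Psi`, `Theta`.
#' @export
standardized_solution <- function(fit) {
  d <- 1 / sqrt(diag(fit$implied))
  Lstd <- fit$Lambda * d
  list(Lambda = Lstd, Psi = fit$Psi, Theta = fit$Theta * d^2)
}

#' @export
print.gsem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Genomic SEM fit (DWLS): chi2(%d) = %.3f, CFI = %.3f, SRMR = %.3f, AIC = %.1f\n",
              x$df, x$chisq, x$cfi, x$srmr, x$aic))
  if (length(x$negative_resid)) {
    cat("  negative residual variance(s):", paste(x$negative_resid, collapse = ", "), "\n")
  }
  print(as.data.frame(dplyr::mutate(x$params, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, digits)))))
  invisible(x)
}
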