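# Weighted straight-line fit y = a + b x with block-deletion estimates
# computed in closed form from per-block sufficient statistics.  Weights are
# held fixed across delete-one-block refits.
wls_line <- function(x, y, w, blocks, intercept_free = TRUE, c0 = 0) {
  sums <- rowsum(cbind(w, w * x, w * y, w * x * x, w * x * y), blocks, reorder = TRUE)
  tot <- colSums(sums)
  solve_cell <- function(s) {
    Sw <- s[, 1]; Sx <- s[, 2]; Sy <- s[, 3]; Sxx <- s[, 4]; Sxy <- s[, 5]
    if (intercept_free) {
      det <- Sw * Sxx - Sx^2
      if (any(det <= 1e-12 * Sw * Sxx)) {
        abort("degenerate design: LD scores carry no variation, slope not identifiable",
              class = "transgsem_degenerate_error")
      }
      b <- (Sw * Sxy - Sx * Sy) / det
      a <- (Sy - b * Sx) / Sw
    } else {
      b <- (Sxy - c0 * Sx) / Sxx
      a <- rep(c0, length(b))
    }
    cbind(a = a, b = b)
  }
  full <- solve_cell(rbind(tot))
  del <- solve_cell(matrix(tot, nrow(sums), 5, byrow = TRUE) - sums)
  list(intercept = unname(full[1, "a"]), slope = unname(full[1, "b"]),
       intercept_del = unname(del[, "a"]), slope_del = unname(del[, "b"]),
       se_intercept = jackknife_se(del[, "a"]), se_slope = jackknife_se(del[, "b"]),
       n_blocks = nrow(sums))
}

# unweighted first pass used both for reporting-free starts and for weights
unweighted_pass <- function(x, y, blocks, intercept_free = TRUE, c0 = 0) {
  wls_line(x, y, rep(1, length(x)), blocks, intercept_free, c0)
}

# LDSC heteroskedasticity/overcounting weights for a chi-square regression:
# 1 / (l * fitted^2), fitted from the unweighted pass, l floored at 1.
h2_weights <- function(l2, x, a0, b0) {
  fitted <- pmax(a0 + b0 * x, 0.1)
  1 / (pmax(l2, 1) * fitted^2)
}

rg_weights <- function(l2_ctx, x_ctx, v1, v2, c0, b0) {
  cov_fit <- c0 + b0 * x_ctx
  1 / (pmax(l2_ctx, 1) * pmax(v1 * v2 + cov_fit^2, 1e-3))
}

# per-trait regressors and unweighted fit, reused by every estimator
h2_parts <- function(panel, trait, blocks, intercept_free = TRUE) {
  ti <- match(trait, panel$traits$trait)
  if (is.na(ti)) abort(sprintf("unknown trait '%s'", trait), class = "transgsem_input_error")
  ctx <- pair_context(panel, trait, trait)
  x <- panel$N[, ti] * ctx$l2 / ctx$M
  y <- panel$Z[, ti]^2
  pass1 <- unweighted_pass(x, y, blocks, intercept_free, c0 = 1)
  v <- pmax(pass1$intercept + pass1$slope * x, 0.1)  # fitted E[chi^2]
  list(ti = ti, x = x, y = y, l2 = ctx$l2, M = ctx$M, pass1 = pass1, v = v)
}

#' Univariate LD score regression
#'
#' Fits `E[chi^2_j] = a + (N h2 / M) * l_j` by weighted least squares with a
#' free (or fixed-at-1) intercept.  Weights follow standard LDSC practice,
#' `1 / (l_j * fitted_j^2)`, initialized from an unweighted pass with one
#' reweighting iteration; standard errors come from a delete-one-block
#' jackknife over contiguous blocks with weights held fixed.
#'
#' @param panel A `harmonized_panel`.
#' @param trait Trait label.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param intercept "free" (default) or "fixed" (constrained to 1).
#' @param weights "ldsc" (default) or "uniform".
#' @param blocks Optional explicit block map.
#' @return An `ldsc_h2` object: `h2`, `intercept`, their SEs, delete-block
#'   values, `n_blocks`, `n_snp`, `M`, `mean_chisq`.
#' @export
estimate_h2 <- function(panel, trait, n_blocks = 200,
                        intercept = c("free", "fixed"),
                        weights = c("ldsc", "uniform"), blocks = NULL) {
  intercept <- match.arg(intercept)
  weights <- match.arg(weights)
  n <- nrow(panel$Z)
  if (n < 200) abort("need at least 200 variants", class = "transgsem_input_error")
  blocks <- blocks %||% assign_blocks(n, n_blocks)
  free <- intercept == "free"
  parts <- h2_parts(panel, trait, blocks, free)
  w <- if (weights == "ldsc") {
    h2_weights(parts$l2, parts$x, parts$pass1$intercept, parts$pass1$slope)
  } else rep(1, n)
  fit <- wls_line(parts$x, parts$y, w, blocks, free, c0 = 1)
  structure(list(trait = trait, h2 = fit$slope, intercept = fit$intercept,
                 se_h2 = fit$se_slope, se_intercept = if (free) fit$se_intercept else 0,
                 h2_del = fit$slope_del, intercept_del = fit$intercept_del,
                 n_blocks = fit$n_blocks, n_snp = n, M = parts$M,
                 mean_chisq = mean(parts$y),
                 intercept_mode = intercept, weights = weights),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LDSC h2 [%s]: %.4f (SE %.4f); intercept %.4f (SE %.4f); mean chi2 %.3f; %d SNPs, %d blocks\n",
              x$trait, x$h2, x$se_h2, x$intercept, x$se_intercept, x$mean_chisq,
              x$n_snp, x$n_blocks))
  invisible(x)
}

# shared bivariate core: regression of z_t z_u on sqrt(N_t N_u) l / M.
# Weights use unweighted first-pass univariate fits for the variance terms
# and the unweighted bivariate pass for the covariance term, so that a trait
# paired with itself reproduces the univariate fit exactly (the weight
# becomes proportional to the univariate weight).
pair_core <- function(panel, trait1, trait2, blocks, intercept_free,
                      weights = "ldsc", parts = NULL) {
  ctx <- pair_context(panel, trait1, trait2)
  t1 <- match(trait1, panel$traits$trait); t2 <- match(trait2, panel$traits$trait)
  x <- sqrt(panel$N[, t1] * panel$N[, t2]) * ctx$l2 / ctx$M
  y <- panel$Z[, t1] * panel$Z[, t2]
  pass1 <- unweighted_pass(x, y, blocks, intercept_free, c0 = 0)
  if (weights == "ldsc") {
    p1 <- parts[[trait1]] %||% h2_parts(panel, trait1, blocks)
    p2 <- parts[[trait2]] %||% h2_parts(panel, trait2, blocks)
    w <- rg_weights(ctx$l2, x, p1$v, p2$v, pass1$intercept, pass1$slope)
  } else w <- rep(1, length(x))
  fit <- wls_line(x, y, w, blocks, intercept_free, c0 = 0)
  c(fit, list(cross = ctx$cross, n_snp = length(x), M = ctx$M))
}

rg_from_parts <- function(rho, rho_del, h2_1, h2_2) {
  if (h2_1$h2 <= 0 || h2_2$h2 <= 0) {
    return(list(rg = NA_real_, se_rg = NA_real_, rg_del = NULL,
                reason = "non-positive heritability estimate"))
  }
  rg <- rho / sqrt(h2_1$h2 * h2_2$h2)
  denom <- h2_1$h2_del * h2_2$h2_del
  rg_del <- ifelse(denom > 0, rho_del / sqrt(pmax(denom, 0)), NA_real_)
  se <- if (anyNA(rg_del)) NA_real_ else jackknife_se(rg_del)
  list(rg = rg, se_rg = se, rg_del = rg_del, reason = NULL)
}

#' Bivariate LD score regression (genetic covariance and correlation)
#'
#' Fits `E[z_t z_u] = c + (sqrt(N_t N_u) rho_g / M) * l_j`, with the
#' cross-trait intercept c free for within-population pairs (it absorbs
#' sample overlap) and fixed to 0 for cross-population pairs (which also
#' use the cross-population LD scores).  The genetic correlation is
#' `rg = rho_g / sqrt(h2_t h2_u)` with the univariate fits computed on the
#' same block map; all SEs are delete-one-block jackknives.
#'
#' @inheritParams estimate_h2
#' @param trait1,trait2 Trait labels.
#' @param intercept `NULL` (default: free within-population, fixed 0
#'   cross-population), "free", or "fixed" (0).
#' @return An `ldsc_rg` object.
#' @export
estimate_rg <- function(panel, trait1, trait2, n_blocks = 200, intercept = NULL,
                        blocks = NULL) {
  n <- nrow(panel$Z)
  blocks <- blocks %||% assign_blocks(n, n_blocks)
  ctx <- pair_context(panel, trait1, trait2)
  free <- if (is.null(intercept)) !ctx$cross else intercept == "free"
  core <- pair_core(panel, trait1, trait2, blocks, free)
  h2_1 <- estimate_h2(panel, trait1, blocks = blocks)
  h2_2 <- estimate_h2(panel, trait2, blocks = blocks)
  rgp <- rg_from_parts(core$slope, core$slope_del, h2_1, h2_2)
  structure(list(trait1 = trait1, trait2 = trait2,
                 rho_g = core$slope, se_rho_g = core$se_slope,
                 rg = rgp$rg, se_rg = rgp$se_rg, rg_del = rgp$rg_del,
                 reason = rgp$reason,
                 intercept = if (core$cross) NA_real_ else core$intercept,
                 se_intercept = if (core$cross) NA_real_ else core$se_intercept,
                 rho_del = core$slope_del, intercept_del = core$intercept_del,
                 cross_population = core$cross, intercept_free = free,
                 h2_1 = h2_1$h2, h2_2 = h2_2$h2,
                 n_blocks = core$n_blocks, n_snp = core$n_snp, M = core$M),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("LDSC rg [%s ~ %s%s]: rg %.4f (SE %.4f); rho_g %.4f (SE %.4f)%s\n",
              x$trait1, x$trait2, if (x$cross_population) ", cross-population" else "",
              x$rg, x$se_rg, x$rho_g, x$se_rho_g,
              if (!x$cross_population)
                sprintf("; intercept %.4f (SE %.4f)", x$intercept, x$se_intercept) else ""))
  invisible(x)
}
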