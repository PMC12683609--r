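#' Assemble the genetic covariance matrix S and its sampling covariance V
#'
#' Builds the T x T genetic covariance matrix (diagonal = univariate LDSC
#' heritabilities, within-population off-diagonals = bivariate LDSC genetic
#' covariances, cross-population cells = the trans-ancestry moment
#' estimator's covariance) and the t* x t* sampling covariance of vech(S),
#' t* = T(T+1)/2, from the joint delete-one-block jackknife: every cell is
#' re-estimated on each leave-block-out subsample over a common block map,
#' so cross-cell sampling dependence is captured.  vech ordering is
#' column-major over the lower triangle including the diagonal
#' (see [vech_index()]).
#'
#' @param panel A `harmonized_panel`.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param blocks Optional explicit block map shared by all cells.
#' @return A `gcov_structure`: `S`, `V`, `traits`, `provenance` (estimator
#'   per cell), `h2` fits, `n_blocks`, and the `vech` index map.
#' @export
build_S_V <- function(panel, n_blocks = 200, blocks = NULL) {
  Tt <- ncol(panel$Z)
  n <- nrow(panel$Z)
  blocks <- blocks %||% assign_blocks(n, n_blocks)
  traits <- panel$traits$trait
  h2_fits <- lapply(traits, function(tr) estimate_h2(panel, tr, blocks = blocks))
  names(h2_fits) <- traits
  parts <- lapply(traits, function(tr) h2_parts(panel, tr, blocks))
  names(parts) <- traits
  idx <- vech_index(Tt)
  tstar <- nrow(idx)
  B <- length(unique(blocks))
  S <- matrix(0, Tt, Tt, dimnames = list(traits, traits))
  prov <- matrix("", Tt, Tt, dimnames = list(traits, traits))
  D <- matrix(0, B, tstar)
  for (c_ in seq_len(tstar)) {
    i <- idx$row[c_]; j <- idx$col[c_]
    if (i == j) {
      f <- h2_fits[[i]]
      S[i, i] <- f$h2; D[, c_] <- f$h2_del; prov[i, i] <- "ldsc_h2"
    } else {
      ctx <- pair_context(panel, traits[i], traits[j])
      core <- pair_core(panel, traits[i], traits[j], blocks,
                        intercept_free = !ctx$cross, parts = parts)
      S[i, j] <- S[j, i] <- core$slope
      D[, c_] <- core$slope_del
      prov[i, j] <- prov[j, i] <- if (ctx$cross) "trans_rg" else "ldsc_rg"
    }
  }
  V <- jackknife_cov(D)
  structure(list(S = S, V = V, traits = panel$traits, provenance = prov,
                 h2_fits = h2_fits, n_blocks = B, n_snp = n,
                 vech = idx, delete_values = D),
            class = "gcov_structure")
}

#' @export
print.gcov_structure <- function(x, ...) {
  Tt <- nrow(x$S)
  cat(sprintf("<gcov_structure> %d traits; V is %d x %d (%d jackknife blocks, %d SNPs)\n",
              Tt, nrow(x$V), ncol(x$V), x$n_blocks, x$n_snp))
  print(round(x$S, 4))
  invisible(x)
}

#' Smooth a symmetric matrix to positive semidefiniteness
#'
#' Eigendecomposes the input, raises eigenvalues below `eps` to `eps`, and
#' reconstructs; a correlation-scale input gets its diagonal re-normalized
#' to 1 afterwards.  The maximum elementwise change is attached as the
#' `max_delta` attribute.
#'
#' @param S Symmetric matrix.
#' @param eps Eigenvalue floor (default 1e-6).
#' @param correlation Is the input on correlation scale?  Default: detected
#'   from a unit diagonal.
#' @return The smoothed matrix.
#' @export
smooth_to_psd <- function(S, eps = 1e-6, correlation = NULL) {
  S <- check_symmetric(S, "S")
  correlation <- correlation %||% all(abs(diag(S) - 1) < 1e-8)
  out <- S
  # diagonal renormalization can push an eigenvalue back below the floor,
  # so clip-and-rescale is iterated until the floor holds
  for (it in 1:20) {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= eps * (1 - 1e-10)) break
    out <- e$vectors %*% diag(pmax(e$values, eps), nrow(S)) %*% t(e$vectors)
    if (correlation) {
      d <- sqrt(diag(out))
      out <- out / outer(d, d)
      diag(out) <- 1
    }
    out <- (out + t(out)) / 2
  }
  dimnames(out) <- dimnames(S)
  attr(out, "max_delta") <- max(abs(out - S))
  out
}

#' Standardize a genetic covariance structure to correlation scale
#'
#' Rescales `S` to `S_corr = D^{-1/2} S D^{-1/2}` with `D = diag(S)` (the
#' heritabilities) and produces the matching sampling covariance `V_corr`.
#'
#' With `v_method = "jackknife"` (default) the off-diagonal cells of
#' `V_corr` come from re-standardizing every delete-one-block replicate of
#' S (each genetic covariance divided by that replicate's heritabilities),
#' so the sampling noise that the normalization itself contributes --
#' including the covariance that cells sharing a trait inherit from that
#' trait's heritability estimate -- is propagated.  With
#' `v_method = "delta"` every V entry is simply rescaled by the product of
#' the two cells' scale factors, treating the scaling as fixed; this is
#' cheaper but overstates the variance of cells whose traits are estimated
#' precisely and understates cross-cell covariance when heritabilities are
#' noisy.  Diagonal (heritability) cells always use the fixed-scale
#' rescaling: the standardized diagonal is exactly 1 by construction, and a
#' literal jackknife of a constant would give those cells zero weight in
#' any diagonally weighted fit.
#'
#' @param structure A `gcov_structure` from [build_S_V()].
#' @param v_method "jackknife" (default) or "delta", see above.
#' @return A `gcor_structure` with `S_corr`, `V_corr`, `scale` factors and
#'   the inherited metadata.
#' @export
standardize <- function(structure, v_method = c("jackknife", "delta")) {
  v_method <- match.arg(v_method)
  S <- structure$S
  h2 <- diag(S)
  if (any(h2 <= 0)) {
    abort(sprintf("non-positive heritability for trait %s",
                  rownames(S)[which(h2 <= 0)[1]]),
          class = "transgsem_input_error")
  }
  d <- sqrt(h2)
  S_corr <- S / outer(d, d)
  idx <- structure$vech
  f <- unname(1 / (d[idx$row] * d[idx$col]))
  V_corr <- structure$V * outer(f, f)
  if (v_method == "jackknife" && !is.null(structure$delete_values)) {
    D <- structure$delete_values
    diag_cells <- which(idx$row == idx$col)
    h2_del <- D[, diag_cells, drop = FALSE]
    if (all(h2_del > 0)) {
      # every column is a function of the same delete-block replicate, so
      # the resulting jackknife covariance is positive semidefinite:
      # off-diagonal cells are re-standardized with that replicate's
      # heritabilities; diagonal cells enter as h2_del / h2_hat, whose
      # jackknife variance equals the fixed-scale value
      denom <- sqrt(h2_del[, idx$row, drop = FALSE] *
                    h2_del[, idx$col, drop = FALSE])
      D_corr <- D / denom
      D_corr[, diag_cells] <- sweep(h2_del, 2, h2, `/`)
      V_corr <- jackknife_cov(D_corr)
    } else {
      warn("non-positive delete-block heritability: falling back to fixed-scale V")
    }
  }
  structure(list(S_corr = S_corr, V_corr = V_corr, scale = f, h2 = h2,
                 traits = structure$traits, provenance = structure$provenance,
                 vech = idx, n_blocks = structure$n_blocks,
                 n_snp = structure$n_snp),
            class = "gcor_structure")
}

#' @export
print.gcor_structure <- function(x, ...) {
  cat(sprintf("<gcor_structure> %d traits on correlation scale\n", nrow(x$S_corr)))
  print(round(x$S_corr, 3))
  invisible(x)
}
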