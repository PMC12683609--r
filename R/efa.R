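promax_rotate <- function(L, power = 4) {
  v <- stats::varimax(L, normalize = TRUE)
  A <- unclass(v$loadings)
  Q <- A * abs(A)^(power - 1)
  U <- solve(crossprod(A), crossprod(A, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), ncol(U))
  pattern <- A %*% U
  Ui <- solve(U)
  Phi <- Ui %*% t(Ui)
  # symmetrize and force exact unit diagonal
  Phi <- (Phi + t(Phi)) / 2; diag(Phi) <- 1
  list(pattern = pattern, Phi = Phi)
}

canonicalize_factors <- function(pattern, Phi) {
  k <- ncol(pattern)
  ord <- order(colSums(pattern^2), decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  for (f in seq_len(k)) {
    if (pattern[which.max(abs(pattern[, f])), f] < 0) {
      pattern[, f] <- -pattern[, f]
      Phi[f, ] <- -Phi[f, ]; Phi[, f] <- -Phi[, f]
    }
  }
  diag(Phi) <- 1
  colnames(pattern) <- colnames(Phi) <- rownames(Phi) <- paste0("F", seq_len(k))
  list(pattern = pattern, Phi = Phi)
}

#' Exploratory factor analysis of a genetic correlation matrix
#'
#' Principal-axis factoring with iterated communalities (starting from
#' squared multiple correlations), followed by an oblique promax rotation
#' (power 4).  Principal-axis extraction is used rather than maximum
#' likelihood because no sample size is well-defined for a genetic
#' correlation matrix.  The result is deterministic given the input;
#' factors are ordered by descending sum of squared loadings and signed so
#' each factor's largest-magnitude loading is positive.  Communalities that
#' hit 1 during iteration mark a Heywood case, which is flagged, not fatal.
#'
#' @param S_corr Smoothed genetic correlation matrix (PSD).
#' @param k Number of factors, `k < T`.
#' @param rotation "promax" (default), "varimax", or "none".
#' @param power Promax power (default 4).
#' @param max_iter,tol Communality iteration controls (100, 1e-6).
#' @return An `efa_result`: `loadings` (pattern), `Phi`, `communality`,
#'   `ss_loadings`, `prop_var`, `k`, `heywood`, `iterations`.
#' @export
efa_fit <- function(S_corr, k, rotation = c("promax", "varimax", "none"),
                    power = 4, max_iter = 100, tol = 1e-6) {
  rotation <- match.arg(rotation)
  R <- check_symmetric(as.matrix(S_corr), "S_corr")
  Tt <- nrow(R)
  if (k >= Tt) abort("k must be smaller than the number of traits",
                     class = "transgsem_input_error")
  traits <- rownames(R) %||% paste0("V", seq_len(Tt))
  h <- tryCatch(pmin(pmax(1 - 1 / diag(solve(R)), 0), 1),
                error = function(e) apply(abs(R - diag(Tt)), 1, max))
  heywood <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    Rr <- R; diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    dvals <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(dvals), k)
    hn <- rowSums(L^2)
    if (any(hn > 1 + tol)) heywood <- TRUE
    hn <- pmin(hn, 1)
    done <- max(abs(hn - h)) < tol || iter >= max_iter
    h <- hn
    if (done) break
  }
  if (rotation == "none" || k == 1 || max(abs(L)) < 1e-12) {
    rot <- list(pattern = L, Phi = diag(k))
  } else if (rotation == "varimax") {
    rot <- list(pattern = unclass(stats::varimax(L, normalize = TRUE)$loadings),
                Phi = diag(k))
  } else {
    rot <- promax_rotate(L, power)
  }
  can <- canonicalize_factors(rot$pattern, rot$Phi)
  rownames(can$pattern) <- traits
  communality <- diag(can$pattern %*% can$Phi %*% t(can$pattern))
  structure(list(loadings = can$pattern, Phi = can$Phi,
                 communality = setNames(communality, traits),
                 ss_loadings = colSums(can$pattern^2),
                 prop_var = colSums(can$pattern^2) / Tt,
                 k = k, rotation = rotation, heywood = heywood,
                 iterations = iter, converged = iter < max_iter),
            class = "efa_result")
}

#' @export
print.efa_result <- function(x, digits = 3, ...) {
  cat(sprintf("EFA: %d factors (%s rotation)%s\n", x$k, x$rotation,
              if (x$heywood) " [Heywood case]" else ""))
  print(round(x$loadings, digits))
  cat("Factor correlations:\n"); print(round(x$Phi, digits))
  invisible(x)
}

#' Scan candidate factor counts
#'
#' Runs [efa_fit()] for each k and summarizes: total genetic variance
#' explained, number of traits with cross-loadings (two or more pattern
#' loadings at or above 0.3 in magnitude), number of weakly determined
#' factors (fewer than two salient loadings), Heywood flags, and a
#' parsimony score (variance explained minus penalties for cross-loadings
#' and weak factors).  The scan is advisory: it never commits to a k.
#'
#' @param S_corr Smoothed genetic correlation matrix.
#' @param k_list Candidate factor counts (default 3, 4, 5).
#' @param salient Salience threshold on |loading| (default 0.3).
#' @return A tibble, one row per k, sorted by descending score.
#' @export
efa_scan <- function(S_corr, k_list = c(3, 4, 5), salient = 0.3) {
  Tt <- nrow(S_corr)
  if (any(k_list >= Tt)) {
    abort("all k must be smaller than the number of traits",
          class = "transgsem_input_error")
  }
  rows <- purrr::map(k_list, function(k) {
    f <- efa_fit(S_corr, k)
    nsal <- rowSums(abs(f$loadings) >= salient)
    n_cross <- sum(nsal >= 2)
    n_weak <- sum(colSums(abs(f$loadings) >= salient) < 2)
    var_tot <- sum(f$communality) / Tt
    tibble(k = k, var_explained = var_tot, n_crossloadings = n_cross,
           n_weak_factors = n_weak, heywood = f$heywood,
           score = var_tot - 0.02 * n_cross - 0.05 * n_weak)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$score))
}

#' Tucker congruence between two loading matrices
#'
#' Factor congruence coefficients after optimal column matching (all column
#' permutations are scored) and sign alignment; useful for comparing
#' recovered loadings with a generating structure.
#'
#' @param A,B Loading matrices with the same dimensions.
#' @return Numeric vector: per-factor congruence of the best matching (all
#'   values in \[0, 1\] after sign alignment), with the permutation as an
#'   attribute.
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(dim(A)[2] == dim(B)[2], dim(A)[1] == dim(B)[1])
  k <- ncol(A)
  cong <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  Cm <- abs(outer(seq_len(k), seq_len(k),
                  Vectorize(function(i, j) cong(A[, i], B[, j]))))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- NULL; best_val <- -Inf
  for (p in perms(seq_len(k))) {
    val <- sum(Cm[cbind(seq_len(k), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  out <- Cm[cbind(seq_len(k), best)]
  attr(out, "permutation") <- best
  out
}
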