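#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm setNames
NULL

# half-vectorization: column-major lower triangle including the diagonal.
# V rows/columns follow this ordering exactly; t* = T(T+1)/2.
vech <- function(M) M[lower.tri(M, diag = TRUE)]

#' Index map of the half-vectorization
#'
#' Row/column indices of each `vech` element, in the fixed column-major
#' lower-triangle order used throughout for the sampling covariance V.
#'
#' @param n_trait Number of traits T.
#' @return A tibble with columns `cell`, `row`, `col` (row >= col).
#' @export
vech_index <- function(n_trait) {
  idx <- which(lower.tri(diag(n_trait), diag = TRUE), arr.ind = TRUE)
  tibble(cell = seq_len(nrow(idx)), row = unname(idx[, 1]), col = unname(idx[, 2]))
}

unvech <- function(v, n_trait) {
  M <- matrix(0, n_trait, n_trait)
  M[lower.tri(M, diag = TRUE)] <- v
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

# contiguous, near-equal blocks over n items
assign_blocks <- function(n, n_blocks) {
  if (n_blocks < 2 || n_blocks > n) {
    abort(sprintf("need 2 <= n_blocks <= n, got n_blocks = %d with n = %d", n_blocks, n),
          class = "transgsem_block_error")
  }
  bounds <- round(seq(0, n, length.out = n_blocks + 1))
  sizes <- diff(bounds)
  if (any(sizes < 1L)) abort("empty jackknife block", class = "transgsem_block_error")
  rep(seq_len(n_blocks), times = sizes)
}

# delete-one-block jackknife SE from the vector of leave-block-out estimates
jackknife_se <- function(del) {
  n <- length(del)
  sqrt((n - 1) / n * sum((del - mean(del))^2))
}

# jackknife covariance of a matrix of leave-block-out estimates (blocks x p)
jackknife_cov <- function(D) {
  B <- nrow(D)
  Dc <- sweep(D, 2, colMeans(D))
  (B - 1) / B * crossprod(Dc)
}

check_symmetric <- function(M, what = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || max(abs(M - t(M))) > tol) {
    abort(sprintf("%s must be symmetric", what), class = "transgsem_input_error")
  }
  (M + t(M)) / 2
}

# deterministic, locale-independent ordering of variant ids
sort_ids <- function(x) sort(x, method = "radix")

#' Generic delete-one-block jackknife
#'
#' Applies a statistic to the data with each contiguous block of rows deleted
#' in turn, and returns the full-sample estimate, jackknife standard error,
#' delete-block values and pseudovalues.
#'
#' @param data A data frame, matrix, or vector whose rows (elements) are
#'   resampling units in a fixed order.
#' @param statistic Function of a data subset returning a numeric scalar or
#'   fixed-length vector.
#' @param n_blocks Number of contiguous blocks (default 200).
#' @param blocks Optional explicit integer block id per row, overriding
#'   `n_blocks`.
#' @return A list with `estimate`, `se`, `delete_values` (blocks x p matrix)
#'   and `pseudovalues`.
#' @export
block_jackknife <- function(data, statistic, n_blocks = 200, blocks = NULL) {
  vec_like <- is.null(dim(data))
  n <- if (vec_like) length(data) else nrow(data)
  blocks <- blocks %||% assign_blocks(n, n_blocks)
  if (length(blocks) != n) abort("block map length mismatch", class = "transgsem_block_error")
  ids <- sort(unique(blocks))
  if (any(tabulate(match(blocks, ids)) == 0L)) {
    abort("empty jackknife block", class = "transgsem_block_error")
  }
  take <- function(keep) if (vec_like) data[keep] else data[keep, , drop = FALSE]
  full <- unname(as.numeric(statistic(data)))
  del <- vapply(ids, function(b) as.numeric(statistic(take(blocks != b))),
                numeric(length(full)))
  del <- if (length(full) == 1) matrix(del, ncol = 1) else t(del)
  B <- length(ids)
  pseudo <- matrix(full, B, length(full), byrow = TRUE) * B - (B - 1) * del
  se <- sqrt((B - 1) / B * colSums(sweep(del, 2, colMeans(del))^2))
  list(estimate = full, se = se, delete_values = del, pseudovalues = pseudo)
}
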