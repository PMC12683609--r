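#' Block LD reference design
#'
#' Describes a genome of `n_blocks` LD blocks of `block_size` variants each.
#' Within a block every pair of variants is correlated `r1` in population 1
#' and `r2` in population 2; across blocks variants are independent.  Under
#' this design every variant in block b has within-population LD score
#' `1 + (m - 1) * r^2` and cross-population LD score `1 + (m - 1) * r1 * r2`.
#'
#' `r1`/`r2` may be scalars (one LD regime genome-wide) or vectors recycled
#' across blocks; a spread of r values gives the LD-score variation that the
#' LD score regression needs to separate slope from intercept.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size Variants per block (m).
#' @param r1,r2 Intra-block correlation per population, in (-1, 1); scalar or
#'   vector recycled over blocks.  `r2` defaults to `r1`.
#' @return An `ld_block_design` object with fields `n_blocks`, `m`, `r1`,
#'   `r2` (length `n_blocks`) and `M = n_blocks * m`.
#' @export
ld_block_design <- function(n_blocks, block_size, r1, r2 = r1) {
  if (n_blocks < 1 || block_size < 1) {
    abort("n_blocks and block_size must be positive", class = "transgsem_design_error")
  }
  r1 <- rep_len(as.numeric(r1), n_blocks)
  r2 <- rep_len(as.numeric(r2), n_blocks)
  if (any(abs(c(r1, r2)) >= 1)) {
    abort("intra-block correlations must satisfy |r| < 1", class = "transgsem_design_error")
  }
  M <- n_blocks * block_size
  if (M < 2) abort("design must contain at least 2 variants", class = "transgsem_design_error")
  structure(list(n_blocks = as.integer(n_blocks), m = as.integer(block_size),
                 r1 = r1, r2 = r2, M = as.integer(M)),
            class = "ld_block_design")
}

variant_ids <- function(M) sprintf("s%07d", seq_len(M))

#' Build LD score panels from a block design
#'
#' Materializes the three LD score panels implied by an [ld_block_design()]:
#' one per population and one cross-population panel, all over the same
#' variant ids.
#'
#' @param design An `ld_block_design`.
#' @return A list with tibbles `pop1`, `pop2`, `cross` (columns CHR, SNP, BP,
#'   L2), the reference variant count `M`, and the per-variant LD block id.
#' @export
build_ld_panels <- function(design) {
  if (!inherits(design, "ld_block_design")) {
    abort("design must be an ld_block_design", class = "transgsem_design_error")
  }
  M <- design$M
  blk <- rep(seq_len(design$n_blocks), each = design$m)
  snp <- variant_ids(M)
  base <- tibble(CHR = 1L, SNP = snp, BP = seq_len(M))
  mk <- function(l2) dplyr::mutate(base, L2 = l2[blk])
  m1 <- design$m - 1
  list(
    pop1  = mk(1 + m1 * design$r1^2),
    pop2  = mk(1 + m1 * design$r2^2),
    cross = mk(1 + m1 * design$r1 * design$r2),
    M = M,
    ld_block = blk
  )
}
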