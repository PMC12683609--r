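#' Trans-ancestry genetic-effect correlation
#'
#' Moment estimator of the cross-population genetic-effect correlation for a
#' pair of traits measured in different populations: regression through the
#' origin of `z_t z_u` on the cross-population LD scores,
#' `E[z_t z_u] = (sqrt(N_t N_u) rho_ge sqrt(h2_t h2_u) / M) * l_cross_j`,
#' with no intercept because samples do not overlap across populations.
#' The slope estimates the cross-population genetic covariance, which is
#' normalized by the two within-population heritabilities (estimated on the
#' same block map) to give `rho_ge`.  Estimates with `|rho_ge| > 1` are
#' reported as-is and flagged, never clipped.
#'
#' @inheritParams estimate_rg
#' @param h2_1,h2_2 Optional precomputed `ldsc_h2` fits for the two traits
#'   (must share the block map); computed internally when omitted.
#' @return A `trans_rg` object: `rho_ge`, `se`, the two heritabilities used
#'   for normalization, variant count, and an `out_of_range` flag.
#' @export
estimate_trans_rg <- function(panel, trait1, trait2, n_blocks = 200,
                              blocks = NULL, h2_1 = NULL, h2_2 = NULL) {
  ctx <- pair_context(panel, trait1, trait2)
  if (!ctx$cross) {
    abort("estimate_trans_rg needs traits from different populations",
          class = "transgsem_context_error")
  }
  n <- nrow(panel$Z)
  blocks <- blocks %||% assign_blocks(n, n_blocks)
  core <- pair_core(panel, trait1, trait2, blocks, intercept_free = FALSE)
  h2_1 <- h2_1 %||% estimate_h2(panel, trait1, blocks = blocks)
  h2_2 <- h2_2 %||% estimate_h2(panel, trait2, blocks = blocks)
  rgp <- rg_from_parts(core$slope, core$slope_del, h2_1, h2_2)
  structure(list(trait1 = trait1, trait2 = trait2,
                 rho_ge = rgp$rg, se = rgp$se_rg, rho_ge_del = rgp$rg_del,
                 reason = rgp$reason,
                 rho_g = core$slope, se_rho_g = core$se_slope,
                 rho_del = core$slope_del,
                 h2_1 = h2_1$h2, h2_2 = h2_2$h2,
                 out_of_range = is.finite(rgp$rg) && abs(rgp$rg) > 1,
                 n_blocks = core$n_blocks, n_snp = core$n_snp, M = core$M),
            class = "trans_rg")
}

#' @export
print.trans_rg <- function(x, ...) {
  cat(sprintf("trans-ancestry rho_ge [%s ~ %s]: %.4f (SE %.4f)%s; h2 = %.3f / %.3f; %d SNPs\n",
              x$trait1, x$trait2, x$rho_ge, x$se,
              if (isTRUE(x$out_of_range)) " [out of range]" else "",
              x$h2_1, x$h2_2, x$n_snp))
  invisible(x)
}
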