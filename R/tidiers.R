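#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn estimate_h2 Tidy the heritability fit into a term table.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.ldsc_h2 <- function(x, ...) {
  tibble(term = c("h2", "intercept"),
         estimate = c(x$h2, x$intercept),
         std.error = c(x$se_h2, x$se_intercept))
}

#' @describeIn estimate_h2 One-row fit summary.
#' @export
glance.ldsc_h2 <- function(x, ...) {
  tibble(trait = x$trait, h2 = x$h2, mean_chisq = x$mean_chisq,
         n_snp = x$n_snp, n_blocks = x$n_blocks, M = x$M)
}

#' @describeIn estimate_rg Tidy the bivariate fit into a term table.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.ldsc_rg <- function(x, ...) {
  tibble(term = c("rg", "rho_g", "intercept"),
         estimate = c(x$rg, x$rho_g, x$intercept),
         std.error = c(x$se_rg, x$se_rho_g, x$se_intercept))
}

#' @describeIn estimate_trans_rg Tidy the trans-ancestry fit.
#' @param x Fitted object.
#' @param ... Unused.
#' @export
tidy.trans_rg <- function(x, ...) {
  tibble(term = c("rho_ge", "rho_g"),
         estimate = c(x$rho_ge, x$rho_g),
         std.error = c(x$se, x$se_rho_g))
}

#' @describeIn build_S_V Tidy the structure into one row per trait pair
#'   with the estimate, jackknife SE and the estimator that produced it.
#' @param x A `gcov_structure`.
#' @param ... Unused.
#' @export
tidy.gcov_structure <- function(x, ...) {
  idx <- x$vech
  tr <- rownames(x$S)
  tibble(trait1 = tr[idx$row], trait2 = tr[idx$col],
         estimate = x$S[cbind(idx$row, idx$col)],
         std.error = sqrt(pmax(diag(x$V), 0)),
         estimator = x$provenance[cbind(idx$row, idx$col)])
}

#' @describeIn standardize Tidy the correlation-scale structure.
#' @param x A `gcor_structure`.
#' @param ... Unused.
#' @export
tidy.gcor_structure <- function(x, ...) {
  idx <- x$vech
  tr <- rownames(x$S_corr)
  tibble(trait1 = tr[idx$row], trait2 = tr[idx$col],
         estimate = x$S_corr[cbind(idx$row, idx$col)],
         std.error = sqrt(pmax(diag(x$V_corr), 0)),
         estimator = x$provenance[cbind(idx$row, idx$col)])
}

#' @describeIn efa_fit Tidy loadings into long format.
#' @param x An `efa_result`.
#' @param ... Unused.
#' @export
tidy.efa_result <- function(x, ...) {
  as_tibble(as.data.frame(x$loadings), rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "factor", values_to = "loading")
}

#' @describeIn efa_fit One-row EFA summary.
#' @export
glance.efa_result <- function(x, ...) {
  tibble(k = x$k, var_explained = sum(x$communality) / length(x$communality),
         heywood = x$heywood, iterations = x$iterations, converged = x$converged)
}

#' @describeIn fit_dwls Tidy the free-parameter table (estimates, sandwich
#'   SEs, Z statistics, two-sided normal p-values).
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @export
tidy.gsem_fit <- function(x, ...) as_tibble(x$params)

#' @describeIn fit_dwls One-row model summary with fit indices.
#' @export
glance.gsem_fit <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, cfi = x$cfi, srmr = x$srmr, aic = x$aic,
         n_free = x$spec$q, converged = x$converged,
         n_negative_resid = length(x$negative_resid))
}
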