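#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_col
#'   geom_errorbar scale_fill_gradient2 labs theme_minimal facet_wrap
#'   coord_flip
#' @export
ggplot2::autoplot

#' Heat map of a genetic correlation structure
#'
#' @param object A `gcor_structure` from [standardize()].
#' @param digits Label rounding (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gcor_structure <- function(object, digits = 2, ...) {
  tr <- rownames(object$S_corr)
  df <- tidy(object)
  df$trait1 <- factor(df$trait1, levels = tr)
  df$trait2 <- factor(df$trait2, levels = rev(tr))
  ggplot(df, aes(x = .data$trait1, y = .data$trait2, fill = .data$estimate)) +
    geom_tile() +
    geom_text(aes(label = round(.data$estimate, digits)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC", high = "#B2182B",
                         mid = "white", name = "rg") +
    labs(x = NULL, y = NULL, title = "Genetic correlations") +
    theme_minimal()
}

#' Loading plot for an exploratory factor analysis
#'
#' @param object An `efa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.efa_result <- function(object, ...) {
  df <- tidy(object)
  df$trait <- factor(df$trait, levels = rev(rownames(object$loadings)))
  ggplot(df, aes(x = .data$factor, y = .data$trait, fill = .data$loading)) +
    geom_tile() +
    geom_text(aes(label = round(.data$loading, 2)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC", high = "#B2182B",
                         mid = "white") +
    labs(x = NULL, y = NULL, title = sprintf("EFA pattern loadings (k = %d)", object$k)) +
    theme_minimal()
}

#' Parameter plot for a fitted confirmatory model
#'
#' Free loadings with +/- 1.96 SE error bars, faceted by factor.
#'
#' @param object A `gsem_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsem_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$type == "loading")
  ggplot(df, aes(x = .data$rhs, y = .data$estimate)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$estimate - 1.96 * .data$std.error,
                      ymax = .data$estimate + 1.96 * .data$std.error),
                  width = 0.25) +
    facet_wrap(~ .data$lhs, scales = "free_x") +
    coord_flip() +
    labs(x = NULL, y = "standardized loading",
         title = sprintf("DWLS factor loadings (CFI %.3f, SRMR %.3f)",
                         object$cfi, object$srmr)) +
    theme_minimal()
}
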