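#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_text facet_wrap labs theme_minimal scale_fill_gradient
#'   geom_hline element_blank theme
NULL

#' @export
ggplot2::autoplot

#' Manhattan-style plot of window variance percentages
#'
#' Each window is drawn at its midpoint position, faceted by trait, with an
#' optional horizontal line at the selection threshold.
#'
#' @param object A `window_variance_tbl` from [aggregate_windows()].
#' @param threshold_pct Optional threshold line (percent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot window_variance_tbl
autoplot.window_variance_tbl <- function(object, threshold_pct = NULL, ...) {
  df <- mutate(as_tibble(object),
               mid_bp = (.data$start_bp + .data$end_bp) / 2,
               chrom = factor(.data$chrom,
                              levels = unique(.data$chrom)[chrom_order(unique(.data$chrom))]))
  gg <- ggplot(df, aes(x = .data$mid_bp / 1e6, y = .data$pct,
                       colour = .data$chrom)) +
    geom_point(size = 0.8) +
    facet_wrap(~ .data$trait, ncol = 1, scales = "free_y") +
    labs(x = "window midpoint (Mb)",
         y = "% of additive genetic variance",
         colour = "chromosome",
         title = sprintf("SNP windows (w = %s, %s)",
                         attr(object, "w"), attr(object, "mode"))) +
    theme_minimal()
  if (!is.null(threshold_pct))
    gg <- gg + geom_hline(yintercept = threshold_pct, linetype = 2)
  gg
}

#' Heatmap of the pairwise scheme comparison
#'
#' @param object A `scheme_comparison`.
#' @param which `"NP"` (shared significant pathways) or `"NG"` (genes in
#'   shared pathways).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot scheme_comparison
autoplot.scheme_comparison <- function(object, which = c("NP", "NG"), ...) {
  which <- match.arg(which)
  df <- tidy(object)
  df$value <- if (which == "NP") df$np else df$ng
  ggplot(df, aes(x = .data$scheme1, y = .data$scheme2,
                 fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = .data$value), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = NULL, y = NULL, fill = which,
         title = sprintf("%s across window schemes", which)) +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Restricted-likelihood trace of a REML fit
#'
#' @param object An `ssgwas_reml` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ssgwas_reml
autoplot.ssgwas_reml <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$iteration, y = .data$logL)) +
    geom_line() +
    geom_point(aes(colour = .data$step), size = 1.5) +
    labs(x = "iteration", y = "restricted log-likelihood",
         colour = "step type") +
    theme_minimal()
}
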