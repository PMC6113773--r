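## ggplot2 displays for the main result types: a forest plot for MR
## estimate tables and a Manhattan-style association plot for
## summary-statistics tables.

#' Forest plot of MR estimates
#'
#' One point and 95% interval per estimator (and per exposure when the
#' table covers several), on the odds-ratio scale with a null reference
#' line.
#'
#' @param object An `osteomr_mr` tibble (see [mr_all()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osteomr_mr <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"exposure" %in% names(df)) df$exposure <- "exposure"
  df$label <- paste(df$exposure, df$method, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style association plot
#'
#' Per-SNP -log10 p-values against position, with the genome-wide
#' significance threshold drawn.
#'
#' @param object A [sumstats()] table.
#' @param p_threshold Reference significance line (default `5e-8`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osteomr_sumstats <- function(object, p_threshold = 5e-8, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$pvalue),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Position (bp)", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
}
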