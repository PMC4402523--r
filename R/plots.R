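#' Plot the base-composition phenotype as [C] versus [A]
#'
#' The canonical view of the phenotype: each point is one individual; PR2
#' puts the cloud on the [C] = 0.5 - [A] diagonal, and a bottleneck-derived
#' group sits shifted towards higher [A] along it.
#'
#' @param object A [base_phenotype()] tibble.
#' @param groups Optional tibble (`sample`, `group`) to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.base_phenotype <- function(object, groups = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(groups)) df <- left_join(df, groups, by = "sample")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = frac_a, y = frac_c)) +
    ggplot2::geom_abline(slope = -1, intercept = 0.5,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "[A] across polymorphic sites",
                  y = "[C] across polymorphic sites") +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = group), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Manhattan-style plot of a genome scan
#'
#' @param object A `scan_result` tibble (with `chrom`/`pos` when available).
#' @param y `"F"` (default) or `"p"` (-log10 p-values).
#' @param threshold Optional horizontal threshold line (F value or -log10 p).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, y = c("F", "p"), threshold = NULL, ...) {
  y <- match.arg(y)
  df <- as_tibble(object)
  if (!all(c("chrom", "pos") %in% names(df))) {
    df$chrom <- "genome"
    df$pos <- seq_len(nrow(df))
  }
  df <- df |>
    arrange(chrom, pos) |>
    group_by(chrom) |>
    mutate(x = pos) |>
    ungroup()
  df$yval <- if (y == "F") df$F else -log10(df$p_value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = yval, colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL,
                  y = if (y == "F") "F statistic" else "-log10(p)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Decay of the allele-switching F distribution
#'
#' @param object A [allele_switch_threshold()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.switch_threshold <- function(object, ...) {
  ggplot2::ggplot(object$distributions,
                  ggplot2::aes(x = factor(proportion), y = F)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::labs(x = "proportion of samples switched",
                  y = "F statistic of the switched pseudo-SNP") +
    ggplot2::theme_minimal()
}
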