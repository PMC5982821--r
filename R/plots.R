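# ggplot2 views of the main result types.

#' Plot a methylation metaprofile
#'
#' One panel per context, profiles around TSS and TTS with a standard-error
#' ribbon.
#'
#' @param profile Output of [metaprofile()]; bind several gene-set profiles
#'   together with a `set` column to overlay them.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(profile) {
  has_set <- "set" %in% names(profile)
  p <- ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$offset_bp, y = .data$mean_level,
                 colour = if (has_set) .data$set else .data$context)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_level - .data$se,
                   ymax = .data$mean_level + .data$se,
                   fill = if (has_set) .data$set else .data$context),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      if (has_set) context ~ anchor else . ~ anchor, scales = "free_y"
    ) +
    ggplot2::labs(x = "distance from anchor (bp, transcribed orientation)",
                  y = "methylation level",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Volcano plot of a differential expression result
#'
#' @param object A `temeth_de` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot temeth_de
autoplot.temeth_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$fdr, 1e-300)),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change (mutant / control)",
                  y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot differential-expression counts along the genome in fixed bins
#'
#' Highlights clusters of DE genes, e.g. cis-linked expression around an
#' introgressed mutation.
#'
#' @param bins Output of [bin_de_counts()].
#' @param locus Optional tibble (`chrom`, `pos`) marking mutation loci.
#' @return A ggplot object.
#' @export
plot_de_bins <- function(bins, locus = NULL) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_start / 1e6,
                                          y = .data$n_de)) +
    ggplot2::geom_col(width = diff(range(bins$bin_start / 1e6)) /
                        max(nrow(bins), 1)) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "DE genes per bin") +
    ggplot2::theme_minimal()
  if (!is.null(locus)) {
    p <- p + ggplot2::geom_vline(
      data = locus, ggplot2::aes(xintercept = .data$pos / 1e6),
      linetype = "dashed", colour = "#d73027"
    )
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
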