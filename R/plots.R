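#' Log-log scatter of segment exon vs NE content
#'
#' @param segments Segment tibble from [split_at_hinges()].
#' @param fit Optional [power_fit][fit_power_law] overlay.
#' @return A ggplot.
#' @export
plot_segment_scaling <- function(segments, fit = NULL) {
  d <- filter(segments, .data$exon_bp > 0, .data$ne_bp > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$exon_bp, .data$ne_bp)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "segment exon content (bp)",
                  y = "segment NE content (bp)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_function(
      fun = function(x) fit$prefactor * x^fit$exponent, colour = "firebrick"
    )
  }
  p
}

#' Observed vs control per-chromosome overlap fractions
#'
#' @param observed,control Tibbles from [overlap_fraction()].
#' @return A ggplot (paired boxplot).
#' @export
plot_enrichment <- function(observed, control) {
  d <- bind_rows(
    mutate(observed, set = "observed"),
    mutate(control, set = "control")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$set, .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "overlap fraction per chromosome")
}
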