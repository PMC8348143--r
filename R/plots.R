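#' Plot window coverage with called (and truth) peaks
#'
#' Coverage is drawn as a step line per chromosome; called peaks as shaded
#' rectangles, and, when given, truth peaks as a rug below the axis — a
#' quick visual check of a peak call.
#'
#' @param coverage Coverage tibble (one or more sample columns; plotted as
#'   the per-window sum).
#' @param peaks Called peak tibble.
#' @param truth Optional truth peak tibble.
#' @param chrom Optional chromosome to restrict the plot to.
#' @return A ggplot object.
#' @export
plot_peak_calls <- function(coverage, peaks, truth = NULL, chrom = NULL) {
  check_interval_cols(coverage, "coverage")
  if (!is.null(chrom)) {
    coverage <- filter(coverage, .data$chrom == !!chrom)
    peaks <- filter(peaks, .data$chrom == !!chrom)
    if (!is.null(truth)) truth <- filter(truth, .data$chrom == !!chrom)
  }
  vals <- coverage_values(coverage)
  df <- tibble(chrom = coverage$chrom, start = coverage$start,
               value = if (ncol(vals) > 1) rowSums(vals) else as.vector(vals))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_step(ggplot2::aes(.data$start, .data$value), linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "window coverage") +
    ggplot2::theme_minimal()
  if (nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2)
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_segment(
      data = truth,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
      colour = "navy", linewidth = 2)
  }
  p
}
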