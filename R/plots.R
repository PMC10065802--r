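#' Tile plot of simulated trajectories
#'
#' Displays level as fill shade over regions (columns) and factors (rows),
#' one panel per timepoint (and per genotype when several are present),
#' echoing the usual presentation of discrete patterning simulations:
#' light shades for weak expression, dark for strong.
#'
#' @param trajectory Tidy trajectory tibble.
#' @return A ggplot object.
#' @examples
#' plot_trajectory(simulate_genotype(terminal_network(), "wt"))
#' @export
plot_trajectory <- function(trajectory) {
  tr <- trajectory
  tr$factor <- factor(tr$factor, levels = rev(levels(factor(tr$factor))))
  p <- ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$region, y = .data$factor, fill = .data$level)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 2)) +
    ggplot2::labs(x = "region", y = NULL, fill = "level") +
    ggplot2::theme_minimal()
  if (length(unique(tr$genotype)) > 1L) {
    p + ggplot2::facet_grid(genotype ~ timepoint,
                            labeller = ggplot2::label_both)
  } else {
    p + ggplot2::facet_wrap(~timepoint, nrow = 1L,
                            labeller = ggplot2::label_both)
  }
}

#' Kymograph of the sequential-segmentation variant
#'
#' Cell (x) by step (y, increasing downwards) grid coloured by phase,
#' showing the posterior-to-anterior progression of the timer-gene
#' succession as the axis grows.
#'
#' @param rows Output of [simulate_wavefront()].
#' @return A ggplot object.
#' @examples
#' plot_kymograph(simulate_wavefront(wavefront_config(n_steps = 10)))
#' @export
plot_kymograph <- function(rows) {
  ph <- cell_phases(rows)
  ggplot2::ggplot(ph, ggplot2::aes(
    x = .data$cell, y = .data$step, fill = .data$phase)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(x = "cell (anterior to posterior)", y = "step",
                  fill = "phase") +
    ggplot2::theme_minimal()
}

#' Line plot of expression traces
#'
#' @param trace An `expression_trace`.
#' @return A ggplot object.
#' @examples
#' plot_trace(synthesize_trace(domain_spec("cad", 70, 85)))
#' @export
plot_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(
    x = .data$position, y = .data$intensity, colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "% egg length (from anterior pole)",
      y = if (is_normalized(trace)) "normalised intensity" else
        "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
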