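# ggplot2 visualizations for the main result types.

#' Plot oriented AP profiles with mean and s.d. bands
#'
#' @param object an `ap_profiles` tibble ([orient_and_normalize()]).
#' @param show_samples draw per-sample traces under the band.
#' @param ... unused.
#' @return A ggplot: position 0 (anterior) to 1 (posterior), mean line with a
#'   standard-deviation ribbon per channel.
#' @exportS3Method ggplot2::autoplot
autoplot.ap_profiles <- function(object, show_samples = FALSE, ...) {
  avg <- average_profiles(object)
  p <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$position, y = .data$mean,
                                         colour = .data$channel,
                                         fill = .data$channel))
  if (show_samples) {
    p <- p + ggplot2::geom_line(
      data = object,
      ggplot2::aes(y = .data$intensity, group = interaction(.data$sample_id, .data$channel)),
      alpha = 0.25, linewidth = 0.3)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "normalized AP position (0 = anterior, 1 = posterior)",
                  y = "normalized intensity", colour = "channel", fill = "channel") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph
#'
#' @param object a [kymograph()].
#' @param ... unused.
#' @return A ggplot raster: AP position on x, time running down the y axis.
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(frame = object$frames,
                           position = object$positions)
  df$intensity <- as.numeric(t(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frame,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "normalized AP position", y = "frame",
                  fill = object$channel) +
    ggplot2::theme_minimal()
}

#' Quiver plot of a flow field
#'
#' @param object a `flow_field` tibble ([klt_flow()] or [time_average_flow()]).
#' @param scale arrow length multiplier.
#' @param ... unused.
#' @return A ggplot of velocity arrows at valid grid points.
#' @exportS3Method ggplot2::autoplot
autoplot.flow_field <- function(object, scale = 3, ...) {
  df <- dplyr::filter(as_tibble(object), .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$col + scale * .data$v_col,
                                       yend = .data$row + scale * .data$v_row),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cluster-correlation matrix
#'
#' @param object a [cluster_correlation()] matrix.
#' @param ... unused.
#' @return A ggplot tile heatmap of Pearson r.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_cor <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("cluster_a", "cluster_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_b, y = .data$cluster_a,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Per-cluster transfer-QC summary plot
#'
#' @param object a [transfer_qc()] result.
#' @param ... unused.
#' @return A ggplot of the three QC statistics per query cluster.
#' @exportS3Method ggplot2::autoplot
autoplot.transfer_qc <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$cluster, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~.data$metric, scales = "free_y") +
    ggplot2::labs(x = "query cluster", y = NULL) +
    ggplot2::theme_minimal()
}
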