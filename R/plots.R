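#' Plot a signaling direction field
#'
#' Arrow plot of per-spot sending or receiving vectors; arrow length is
#' proportional to signal magnitude.
#'
#' @param object a [signal_field][signaling_direction].
#' @param direction `"sent"` or `"received"`.
#' @param arrow_scale multiplier applied to vectors for display (default
#'   auto-scaled so the longest arrow spans about two median spot spacings).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.signal_field <- function(object, direction = c("sent", "received"),
                                  arrow_scale = NULL, ...) {
  direction <- match.arg(direction)
  V <- if (direction == "sent") object$Vs else object$Vr
  df <- tibble(x = object$coords[, 1], y = object$coords[, 2],
               vx = V[, 1], vy = V[, 2])
  vmax <- max(sqrt(df$vx^2 + df$vy^2))
  if (is.null(arrow_scale)) {
    spacing <- median(stats::dist(object$coords[
      seq_len(min(200, nrow(object$coords))), , drop = FALSE]))
    arrow_scale <- if (vmax > 0) 2 * spacing / vmax else 1
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, colour = "grey70") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$vx,
                   yend = .data$y + arrow_scale * .data$vy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Signaling direction:", direction)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-level communication network as a heatmap
#'
#' Tile map of mean cluster-to-cluster signaling strength; tiles significant
#' at `alpha` are outlined.
#'
#' @param object a [cluster_network][cluster_communication].
#' @param alpha significance threshold for outlining (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cluster_network <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$sig <- !is.na(df$pval) & df$pval < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dst, y = .data$src,
                                   fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$sig, ], fill = NA, colour = "black",
                       linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "receiving cluster", y = "sending cluster",
                  fill = "strength",
                  title = sprintf("Cluster communication (outline: p < %g)", alpha)) +
    ggplot2::theme_minimal()
}

#' Map total sent and received signal over the tissue
#'
#' @param object a `ccc_tensor`.
#' @param ... unused.
#' @return a ggplot, spots colored by total sent and received signal.
#' @export
autoplot.ccc_tensor <- function(object, ...) {
  if (is.null(object$coords)) abort("tensor has no coordinates to plot")
  tot <- received_sent_totals(total_matrix(object), spots = object$spots)
  df <- tidyr::pivot_longer(
    dplyr::mutate(tot, x = object$coords[, 1], y = object$coords[, 2]),
    c("sent", "received"), names_to = "direction", values_to = "signal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$signal)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
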