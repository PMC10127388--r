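# ggplot2 views of the main result types.

#' @export
autoplot.density_map <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(m)) - 0.5, each = nrow(m)),
    y = rep(seq_len(nrow(m)) - 0.5, ncol(m)),
    density = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "grid x", y = "grid y",
                  title = sprintf("predicted count %.1f", sum(m)))
}

#' @export
plot.density_map <- function(x, ...) print(autoplot.density_map(x, ...))

#' @export
autoplot.rape_scene <- function(object, show_points = TRUE, ...) {
  img <- object$image
  hex <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(hex) <- dim(img)[1:2]
  H <- nrow(hex); W <- ncol(hex)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(hex, xmin = 0, xmax = W, ymin = -H, ymax = 0) +
    ggplot2::xlim(0, W) + ggplot2::ylim(-H, 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]",
                  title = sprintf("synthetic scene, %d clusters",
                                  nrow(object$points)))
  if (show_points && nrow(object$points) > 0) {
    df <- tibble::tibble(x = object$points$x, y = -object$points$y)
    p <- p + ggplot2::geom_point(data = df,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 colour = "red", shape = 3, size = 1)
  }
  p
}

#' @export
autoplot.evaluation_set <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$manual, y = .data$inferred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "manual count", y = "inferred count")
}

#' @export
autoplot.rape_fit <- function(object, ...) {
  lg <- tidyr::pivot_longer(object$log, c("loss", "val_mae"),
                            names_to = "series", values_to = "value")
  lg <- lg[!is.na(lg$value), ]
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL)
}
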