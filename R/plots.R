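# ggplot2 visualisations for the result objects

#' @export
autoplot.marker_similarity <- function(object, ...) {
  df <- tidy(object)
  ord <- object$markers
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$marker_a, levels = ord),
    y = factor(.data$marker_b, levels = rev(ord)),
    fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|rho|") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise-complete |Spearman| similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
autoplot.elbow_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "Component", y = "Mean eigenvalue",
                  title = sprintf("Permutation-averaged scree (k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.feature_weights <- function(object, ...) {
  df <- object$weights
  df$marker <- factor(df$marker, levels = rev(df$marker))
  ggplot2::ggplot(df, ggplot2::aes(.data$rescaled, .data$marker,
                                   fill = .data$weak)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8",
                                          `TRUE` = "grey70"),
                               name = "Weak (< 0.5)") +
    ggplot2::labs(x = "Predictor strength (rescaled to [0, 1])", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wpgma_dendrogram <- function(object, ...) {
  hc <- as.hclust(object)
  # leaf x-positions in plotting order
  p <- length(object$labels)
  xpos <- numeric(p)
  xpos[object$order] <- seq_len(p)
  node_x <- numeric(p - 1)
  node_y <- object$height
  seg <- list()
  pos_of <- function(id) if (id < 0) c(xpos[-id], 0) else c(node_x[id], node_y[id])
  for (s in seq_len(p - 1)) {
    a <- pos_of(object$merge[s, 1])
    b <- pos_of(object$merge[s, 2])
    node_x[s] <- (a[1] + b[1]) / 2
    seg[[length(seg) + 1]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[s], node_y[s]), yend = c(node_y[s], node_y[s], b[2]))
  }
  segs <- dplyr::bind_rows(seg)
  leaves <- tibble::tibble(x = xpos, label = object$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "Linkage distance (1 - |rho|)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}
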