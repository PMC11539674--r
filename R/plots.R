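#' Fixed qualitative palette for group colouring
#'
#' Deterministic colours indexed by group id, shared by dendrogram, biplot
#' and heatmap displays so that a group keeps its colour across figures.
#'
#' @param k Number of groups.
#' @return Character vector of `k` colours.
#' @export
group_palette <- function(k) {
  pal <- c("#1f77b4", "#2ca02c", "#d62728", "#9467bd", "#ff7f0e",
           "#8c564b", "#e377c2", "#17becf", "#bcbd22", "#7f7f7f")
  rep_len(pal, k)
}

dendro_segments <- function(tree) {
  n <- length(tree$labels)
  xpos <- numeric(n)
  xpos[tree$order] <- seq_len(n)
  nx <- numeric(n - 1)  # x of each internal node
  ny <- tree$height
  segs <- list()
  node_x <- function(v) if (v < 0) xpos[-v] else nx[v]
  node_y <- function(v) if (v < 0) 0 else ny[v]
  for (v in seq_len(n - 1)) {
    x1 <- node_x(tree$merge[v, 1]); x2 <- node_x(tree$merge[v, 2])
    y1 <- node_y(tree$merge[v, 1]); y2 <- node_y(tree$merge[v, 2])
    nx[v] <- (x1 + x2) / 2
    segs[[v]] <- tibble::tibble(
      x = c(x1, x1, x2), xend = c(x1, x2, x2),
      y = c(y1, ny[v], ny[v]), yend = c(ny[v], ny[v], y2))
  }
  dplyr::bind_rows(segs)
}

#' Plot a dendrogram, optionally coloured by groups
#'
#' @param tree A `band_dendro`/`hclust` object (seriate first with
#'   [seriate_dendrogram()] for a readable base order).
#' @param groups Optional tibble `label`, `group` (from [cut_groups()])
#'   used to colour the leaf labels.
#' @param label_size Text size for leaf labels.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, groups = NULL, label_size = 2.5) {
  n <- length(tree$labels)
  leaves <- tibble::tibble(label = tree$labels[tree$order], x = seq_len(n), y = 0)
  if (!is.null(groups)) {
    leaves$group <- factor(groups$group[match(leaves$label, groups$label)])
  }
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = dendro_segments(tree),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous("dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor.x = ggplot2::element_blank())
  if (is.null(groups)) {
    gg + ggplot2::geom_text(data = leaves,
                            ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                            angle = 90, hjust = 1.1, size = label_size)
  } else {
    gg + ggplot2::geom_text(data = leaves,
                            ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                                         colour = .data$group),
                            angle = 90, hjust = 1.1, size = label_size) +
      ggplot2::scale_colour_manual(values = group_palette(nlevels(leaves$group)))
  }
}

#' Plot one classification-enhanced biplot panel
#'
#' Accessions are drawn as labelled points and bands as arrows from the
#' origin, both coloured by their dendrogram groups.
#'
#' @param coords Output of [biplot_coords()].
#' @param pair Which component pair to draw, e.g. `"PC1-PC2"` (default: the
#'   first pair present).
#' @param arrow_scale Multiplier applied to band arrows for display.
#' @return A ggplot object.
#' @export
plot_biplot <- function(coords, pair = NULL, arrow_scale = 1) {
  if (is.null(pair)) pair <- coords$pair[1]
  cc <- dplyr::filter(coords, .data$pair == !!pair)
  if (nrow(cc) == 0) stop("no coordinates for pair ", pair, call. = FALSE)
  pts <- dplyr::filter(cc, .data$type == "accession")
  arr <- dplyr::filter(cc, .data$type == "band")
  ngrp <- max(cc$group)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = arr,
                          ggplot2::aes(x = 0, y = 0,
                                       xend = arrow_scale * .data$x,
                                       yend = arrow_scale * .data$y,
                                       colour = factor(.data$group)),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                                    colour = factor(.data$group)),
                       size = 2.5) +
    ggplot2::scale_colour_manual("group", values = group_palette(ngrp)) +
    ggplot2::labs(x = sub("-.*", "", pair), y = sub(".*-", "", pair)) +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram-ordered heatmap of band scores
#'
#' White tiles mark absent bands and blue tiles present bands; rows and
#' columns follow the orders of their dendrograms when the matrix comes
#' from [heatmap_order()].
#'
#' @param x A band matrix tibble, typically already reordered.
#' @return A ggplot object.
#' @export
plot_band_heatmap <- function(x) {
  x <- validate_band_matrix(x)
  long <- tidyr::pivot_longer(x, -"accession", names_to = "band",
                              values_to = "present")
  long$accession <- factor(long$accession, rev(x$accession))
  long$band <- factor(long$band, names(x)[-1])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$band, y = .data$accession,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#1f77b4"),
                               guide = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_text(size = 5),
                   axis.title = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Scree plot of a PCA
#'
#' @param object A `band_pca` object.
#' @param n_components Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_pca <- function(object, n_components = 10, ...) {
  gl <- utils::head(glance(object), n_components)
  gl$component <- factor(gl$component, gl$component)
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$component, y = 100 * .data$prop_var)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(y = "% of variation", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
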