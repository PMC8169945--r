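# ggplot2 figures for the result objects.

#' Plot the variance-scaled PCA embedding
#'
#' @param object an `hsp_pca`.
#' @param ... unused.
#' @return a ggplot: one labelled point per subnetwork, axes annotated
#'   with the explained-variance fractions the coordinates were scaled by.
#' @method autoplot hsp_pca
#' @export
autoplot.hsp_pca <- function(object, ...) {
  v <- object$var_explained
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("PC1 × %.3f", v[1]),
                  y = sprintf("PC2 × %.3f", v[2])) +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram with AU branch support
#'
#' @param object an `hsp_au`.
#' @param au_threshold branches with AU above this are labelled in bold
#'   red.
#' @param ... unused.
#' @return a ggplot dendrogram with AU values printed at internal nodes.
#' @method autoplot hsp_au
#' @export
autoplot.hsp_au <- function(object, au_threshold = 0.9, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  pos <- matrix(0, nrow(hc$merge), 2) # x, y of each internal node
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    xy <- vapply(hc$merge[i, ], function(child) {
      if (child < 0) c(leaf_x[[as.character(-child)]], 0)
      else pos[child, ]
    }, numeric(2))
    pos[i, ] <- c(mean(xy[1, ]), hc$height[i])
    segs[[i]] <- tibble(
      x = c(xy[1, 1], xy[1, 1], xy[1, 2]),
      xend = c(xy[1, 1], xy[1, 2], xy[1, 2]),
      y = c(xy[2, 1], hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], xy[2, 2]))
  }
  seg_tbl <- bind_rows(segs)
  node_tbl <- tibble(x = pos[, 1], y = pos[, 2], au = object$branches$au)
  leaves <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg_tbl,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = node_tbl,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sprintf("%.2f", .data$au),
                                    colour = .data$au > au_threshold),
                       vjust = -0.4, size = 3, show.legend = FALSE) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       vjust = 1.5, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30")) +
    ggplot2::labs(x = NULL, y = "height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar chart of a block profile
#'
#' @param profile a tibble from [block_profile()].
#' @return a ggplot of percentages per functional block.
#' @export
plot_block_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = stats::reorder(.data$block, -.data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of enriched terms") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Diverging bar chart of block fold changes
#'
#' @param fold_changes a tibble from [profile_fold_change()] (optionally
#'   with a `cluster` column for facetting).
#' @param clamp the display bound used when computing the fold changes.
#' @return a ggplot.
#' @export
plot_fold_change <- function(fold_changes, clamp = 25) {
  p <- ggplot2::ggplot(fold_changes,
                       ggplot2::aes(x = .data$block, y = .data$fold_change)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::coord_flip(ylim = c(-clamp, clamp)) +
    ggplot2::labs(x = NULL, y = "fold change vs core profile") +
    ggplot2::theme_minimal()
  if ("cluster" %in% names(fold_changes)) {
    p <- p + ggplot2::facet_wrap(~cluster)
  }
  p
}

#' Line plot of mean silhouette width per cluster count
#'
#' @param silhouette the list returned by [select_k_silhouette()].
#' @return a ggplot with the chosen k highlighted.
#' @export
plot_silhouette <- function(silhouette) {
  ggplot2::ggplot(silhouette$scores,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = silhouette$best_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}
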