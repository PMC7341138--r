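## ggplot2 display of promoter matrices and average profiles. Plots are
## conveniences; the tested artifacts are the matrices themselves.

#' Heatmap of a promoter matrix
#'
#' Rows in their current sort order (top row first), columns the window
#' offsets. Sensitivity-like matrices (values spanning zero) use a
#' blue-black-yellow diverging scale (MRF blue, MSF yellow); non-negative
#' matrices a white-to-blue scale.
#'
#' @param object a [promoter_matrix()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.promoter_matrix <- function(object, ...) {
  long <- tidy(object)
  long$gene_id <- factor(long$gene_id, levels = rev(object$gene_id))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$offset,
                                          y = .data$gene_id,
                                          fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "offset from TSS (bp)", y = NULL,
                  title = pm_meta(object)$label) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  rng <- range(long$value, na.rm = TRUE)
  if (rng[1] < 0 && rng[2] > 0) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                      high = "yellow", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_gradient(low = "white", high = "darkblue")
  }
}

#' Average profile plot per cluster or quartile
#'
#' @param profiles a `profile_summary` from [cluster_average_profiles()].
#' @return a ggplot object.
#' @export
plot_cluster_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$offset, y = .data$value,
                                         colour = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from TSS (bp)", y = "mean signal",
                  colour = "group") +
    ggplot2::theme_minimal()
}
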