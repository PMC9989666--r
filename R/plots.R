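# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.ignition_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$mean_idi))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$region, .data$mean_idi), y = .data$mean_idi)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean intrinsic-driven ignition (regions)",
                  title = "Ignition profile") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fcd_matrix <- function(object, ...) {
  M <- unclass(object)
  df <- tidyr::expand_grid(x = seq_len(nrow(M)), y = seq_len(ncol(M)))
  df$r <- M[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "window", y = "window", fill = "FC similarity",
                  title = "Functional connectivity dynamics") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.global_emergence <- function(object, ...) {
  M <- object$capacity_matrix
  df <- tidyr::expand_grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$capacity <- M[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$capacity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "region", y = "region", fill = "bits",
                  title = "Pairwise emergence capacity") +
    ggplot2::theme_minimal()
}

#' Violin/box plot of per-subject measures by group
#'
#' @param results tidy results tibble from [run_subject_measures()].
#' @param measures optional subset of measures to plot.
#' @return a ggplot object (facetted by measure).
#' @export
plot_group_measures <- function(results, measures = NULL) {
  df <- dplyr::filter(results, !is.na(.data$value))
  if (!is.null(measures)) df <- dplyr::filter(df, .data$measure %in% measures)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value, fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.2, outlier.shape = NA, alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.6) +
    ggplot2::facet_wrap(~ measure, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
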