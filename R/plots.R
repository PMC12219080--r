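#' Plot a grayscale image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot raster panel with the radiological top-down orientation.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, object$max_value)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "I")
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_result` from [crossvalidate()].
#' @param ... Unused.
#' @return A ggplot: one point per fold and metric, with the fold means.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value", colour = "fold")
}

#' Volcano-style view of per-feature class separation
#'
#' @param comparison Tibble from [compare_feature_groups()].
#' @param alpha Significance line. Default 0.05.
#' @return A ggplot of mean difference versus -log10 p.
#' @export
plot_feature_comparison <- function(comparison, alpha = 0.05) {
  df <- dplyr::mutate(comparison,
                      diff = .data$mean_abnormal - .data$mean_normal,
                      neglogp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$diff, .data$neglogp)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "abnormal - normal mean difference",
                  y = expression(-log[10]~p))
}
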