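#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean_pair = object$mean_pair, diff = object$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two measurements",
                  y = "Difference (a - m)",
                  title = sprintf("Bland-Altman: bias %.3g, 95%% LoA (%.3g, %.3g)",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flr_cohort_report <- function(object, ...) {
  df <- object$flr_measurements
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$flr_pct,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "FLR (%)",
                  title = "FLR% by setting and segmentation method") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a label volume
#'
#' @param volume A [label_volume].
#' @param k Slice index along the third axis (defaults to the middle).
#' @return A ggplot object.
#' @export
plot_phantom_slice <- function(volume, k = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$grid)
  if (is.null(k)) k <- round(d[3] / 2)
  sl <- volume$grid[, , k]
  inv <- stats::setNames(names(volume$label_map), volume$label_map)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$label <- factor(ifelse(c(sl) == 0, "background", inv[as.character(c(sl))]),
                     levels = c("background", names(volume$label_map)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(title = sprintf("Axial slice k = %d", k)) +
    ggplot2::theme_void()
}
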