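#' Plot a point cloud projection
#'
#' Side (x-z) scatter of the cloud, colored by label when present.
#'
#' @param object A `point_cloud`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_cloud <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)")
  if ("label" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$label,
                                                        levels = c(0, 1),
                                                        labels = c("stem", "silique"))),
                            size = 0.3, alpha = 0.6) +
      ggplot2::labs(color = NULL)
  } else {
    p + ggplot2::geom_point(size = 0.3, alpha = 0.6)
  }
}

#' Plot fitted silique lines
#'
#' Side view of the fitted line models: each pod drawn as a segment of its
#' fitted axis over its inlier extent.
#'
#' @param object A `silique_lines` tibble from [count_siliques()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silique_lines <- function(object, ...) {
  df <- as_tibble(object)
  seg <- dplyr::mutate(df,
                       x0 = .data$anchor_x - .data$length / 2 * .data$dir_x,
                       z0 = .data$anchor_z - .data$length / 2 * .data$dir_z,
                       x1 = .data$anchor_x + .data$length / 2 * .data$dir_x,
                       z1 = .data$anchor_z + .data$length / 2 * .data$dir_z)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$z0,
                                       xend = .data$x1, yend = .data$z1,
                                       color = factor(.data$silique_id)),
                          linewidth = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)",
                  title = paste(nrow(df), "siliques identified"))
}

#' Plot a count report
#'
#' Identified versus true counts per plant with the identity line; the R
#' squared shown is the identity-prediction coefficient of determination.
#'
#' @param object A `count_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_report <- function(object, ...) {
  df <- object$per_plant
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_count,
                                   y = .data$correct_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "true silique count", y = "identified silique count",
                  subtitle = sprintf("precision %.2f%%, MAPE %.2f%%, R² %.3f",
                                     object$totals$precision_percent,
                                     object$mape_percent, object$r_squared))
}

#' Plot a training log
#'
#' Train/validation loss and validation accuracy per epoch.
#'
#' @param object A trained `dgcnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dgcnn_model <- function(object, ...) {
  if (is.null(object$log)) abort("model has no training log")
  df <- tidyr_longer_log(object$log)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL)
}

tidyr_longer_log <- function(log) {
  dplyr::bind_rows(
    tibble(epoch = log$epoch, metric = "train_loss", value = log$train_loss),
    tibble(epoch = log$epoch, metric = "val_loss", value = log$val_loss),
    tibble(epoch = log$epoch, metric = "val_acc", value = log$val_acc)
  )
}
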