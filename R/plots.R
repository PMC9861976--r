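#' Plot an en face map
#'
#' Raster display in physical millimetres, one row per B-scan. Binary maps
#' render as presence/absence; confidence and intensity maps as a
#' continuous fill.
#'
#' @param object An [enface_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enface_map <- function(object, ...) {
  g <- attr(object, "geometry")
  kind <- attr(object, "kind")
  df <- tibble::tibble(
    x_mm = rep((seq_len(ncol(object)) - 0.5) * g$field_x_mm / ncol(object),
               each = nrow(object)),
    y_mm = rep((seq_len(nrow(object)) - 0.5) * g$field_y_mm / nrow(object),
               times = ncol(object)),
    value = as.numeric(unclass(object))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = kind,
                  title = paste("En face", kind, "map"))
  if (kind %in% c("truth", "prediction")) {
    p <- p + ggplot2::scale_fill_gradient(low = "black", high = "green3",
                                          guide = "none")
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "black", high = "white")
  }
  p
}

#' Plot a lesion report as a graded en face overlay
#'
#' Lesions colored by CAM grade: cRORA (meets the 250-um greatest linear
#' dimension) in green, iRORA in blue.
#'
#' @param object A `lesion_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lesion_report <- function(object, ...) {
  g <- object$geometry
  px <- dplyr::left_join(object$pixels,
                         object$lesions[, c("label", "cam_class")],
                         by = "label")
  ggplot2::ggplot(px, ggplot2::aes(
    (.data$ascan_index + 0.5) * g$um_per_px_x / 1000,
    (.data$bscan_index + 0.5) * g$um_per_px_y / 1000,
    fill = .data$cam_class)) +
    ggplot2::geom_tile(width = g$um_per_px_x / 1000,
                       height = g$um_per_px_y / 1000) +
    ggplot2::scale_fill_manual(values = c(cRORA = "green3",
                                          iRORA = "royalblue")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::lims(x = c(0, g$field_x_mm), y = c(g$field_y_mm, 0)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "CAM grade")
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Pixel-wise ROC (AUC = %.3f)",
                                  object$auc))
}

#' Plot a training history
#'
#' @param object A `training_history` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.training_history <- function(object, ...) {
  df <- tibble::tibble(
    epoch = rep(object$epoch, 2),
    loss = c(object$train_loss, object$val_loss),
    set = rep(c("train", "validation"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_epoch"),
                        linetype = "dotted") +
    ggplot2::labs(y = "Binary cross-entropy")
}
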