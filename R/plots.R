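# ggplot2 views and broom-style summaries of fitted objects.

#' @method autoplot cs_training_curve
#' @export
autoplot.cs_training_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$decayed),
                        color = "firebrick", size = 2) +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "Training curve (red points: learning-rate decay)") +
    ggplot2::theme_minimal()
}

#' @method autoplot cs_ablation_report
#' @export
autoplot.cs_ablation_report <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(radius = object$radius, metric = "accuracy", value = object$accuracy),
    tibble::tibble(radius = object$radius, metric = "AUC", value = object$auc)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$radius, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dilation radius (voxels)", y = NULL,
                  title = "Lesion-periphery dilation ablation") +
    ggplot2::theme_minimal()
}

#' Training curve of a fitted network
#'
#' @param x A model returned by [train_segmenter()] or [train_fusion()].
#' @param ... Unused.
#' @return The per-epoch tibble (`epoch`, `loss`, `lr`, `decayed`).
#' @method tidy segnet
#' @export
tidy.segnet <- function(x, ...) {
  cv <- attr(x, "curve")
  if (is.null(cv)) stop_cs("model has no training curve (untrained?)", "cs_argument_error")
  cv
}

#' @rdname tidy.segnet
#' @method tidy fusion_net
#' @export
tidy.fusion_net <- tidy.segnet

#' One-row summary of a fitted network
#'
#' @param x A `segnet` or `fusion_net`.
#' @param ... Unused.
#' @return A one-row tibble with parameter count, epochs trained, and final
#'   training loss.
#' @method glance segnet
#' @export
glance.segnet <- function(x, ...) {
  cv <- attr(x, "curve")
  tibble::tibble(
    n_parameters = n_params(segnet_layers(x)),
    epochs = if (is.null(cv)) 0L else nrow(cv),
    final_loss = if (is.null(cv)) NA_real_ else cv$loss[nrow(cv)],
    final_lr = if (is.null(cv)) NA_real_ else cv$lr[nrow(cv)]
  )
}

#' @rdname glance.segnet
#' @method glance fusion_net
#' @export
glance.fusion_net <- function(x, ...) {
  cv <- attr(x, "curve")
  tibble::tibble(
    n_parameters = n_params(fusion_layers(x)),
    epochs = if (is.null(cv)) 0L else nrow(cv),
    final_loss = if (is.null(cv)) NA_real_ else cv$loss[nrow(cv)],
    final_lr = if (is.null(cv)) NA_real_ else cv$lr[nrow(cv)]
  )
}
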