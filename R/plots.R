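# ggplot2 visualisations for the fitted model, evaluation reports and the
# accuracy-versus-window curve.

#' Plot the training log of a CNN fit
#'
#' Loss and training accuracy (and validation curves when present) by epoch.
#'
#' @param object A trained `cnn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cnn_model
#' @export
autoplot.cnn_model <- function(object, ...) {
  log <- tidy(object)
  if (nrow(log) == 0) {
    abort_state("No training log to plot; train the model first.")
  }
  long <- tidyr::pivot_longer(
    log, -"epoch",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "epoch", y = NULL, colour = NULL,
      title = "CNN training log"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a confusion heatmap
#'
#' Row-normalised confusion matrix (rows = true class) with counts overlaid.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("truth", "predicted", "n")
  df <- dplyr::group_by(df, .data$truth)
  df <- dplyr::mutate(df, rate = .data$n / max(1, sum(.data$n)))
  df <- dplyr::ungroup(df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$truth, fill = .data$rate
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(
      low = "white", high = "steelblue", limits = c(0, 1)
    ) +
    ggplot2::labs(
      x = "predicted class", y = "true class", fill = "row rate",
      title = sprintf("Window-level confusion (accuracy %.3f)", object$accuracy)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the accuracy-versus-window-size curve
#'
#' @param curve Tibble from [accuracy_vs_frames()].
#' @param highlight Window size to mark (default 30, the operating point).
#' @return A ggplot.
#' @export
plot_frame_curve <- function(curve, highlight = 30) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$K, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "window size (frames)", y = "window accuracy",
      title = "Accuracy per ensemble window size"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(highlight) && highlight %in% curve$K) {
    p <- p + ggplot2::geom_vline(
      xintercept = highlight, linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' Plot a pose frame or sequence as a stick figure
#'
#' A quick sagittal-plane (x--y) view of landmark positions, faceted by
#' frame. Intended for eyeballing simulated or loaded sequences.
#'
#' @param seq A [pose_sequence()].
#' @param frames Frame indices to show (default the first frame).
#' @return A ggplot.
#' @export
plot_pose <- function(seq, frames = NULL) {
  if (!inherits(seq, "pose_sequence")) seq <- pose_sequence(seq)
  frames <- frames %||% seq$frame[[1]]
  df <- dplyr::filter(seq, .data$frame %in% frames)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~frame) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = seq$sequence_id[[1]])
}
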