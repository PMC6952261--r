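#' Plot a chunk-level ROC sweep
#'
#' Sensitivity against 1 - specificity over the threshold grid.
#'
#' @param object A [chunk_metrics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chunk_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tau)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", colour = "tau",
                  title = "Chunk-level classification over the threshold grid") +
    ggplot2::theme_minimal()
}

#' Plot learning curves of a fit
#'
#' @param object A `polyp_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and validation metrics per epoch.
#' @export
autoplot.polyp_fit <- function(object, ...) {
  logs <- tidyr::pivot_longer(object$logs,
                              c("train_loss", "validation_accuracy",
                                "validation_sensitivity", "validation_specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(logs, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Learning curves") +
    ggplot2::theme_minimal()
}

#' Plot a post-processed score sequence
#'
#' Shows the per-chunk polyp probability of one video, the threshold, the
#' surviving post-processed labels, and (optionally) the ground-truth polyp
#' scenes as shaded spans.
#'
#' @param data A [postprocess_scores()] result filtered to one video.
#' @param tau The threshold that produced `flag`.
#' @param gt_scenes Optional tibble with `start_frame`, `end_frame`, `label`.
#' @param stride,chunk_len Chunk timing (frames) used to place ground truth
#'   on the chunk axis.
#' @return A ggplot.
#' @export
plot_score_sequence <- function(data, tau = 0.5, gt_scenes = NULL,
                                stride = 12, chunk_len = 16) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$chunk_index))
  if (!is.null(gt_scenes)) {
    gt <- gt_scenes[gt_scenes$label == "polyp", , drop = FALSE]
    if (nrow(gt) > 0) {
      gt$xmin <- gt$start_frame / stride
      gt$xmax <- (gt$end_frame - chunk_len) / stride
      p <- p + ggplot2::geom_rect(
        data = gt,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
        ymin = -Inf, ymax = Inf, fill = "red", alpha = 0.15,
        inherit.aes = FALSE)
    }
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$polyp_prob)) +
    ggplot2::geom_hline(yintercept = tau, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$keep * 1.02,
                                     alpha = factor(.data$keep)),
                        shape = 15, colour = "firebrick", show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`0` = 0, `1` = 1)) +
    ggplot2::labs(x = "chunk index", y = "polyp probability",
                  title = unique(data$video_id)[1]) +
    ggplot2::theme_minimal()
}
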