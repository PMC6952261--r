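#' Chunk-level sensitivity/specificity over a threshold grid
#'
#' At each threshold, a chunk is called polyp iff its probability is strictly
#' greater than `tau`; sensitivity is the flagged fraction of true polyp
#' chunks and specificity the rejected fraction of non-polyp chunks. The
#' default grid is 0.05 to 0.95 in steps of 0.05.
#'
#' @param data Tibble with columns `prob_polyp` and `label`
#'   (`"polyp"`/`"nonpolyp"`), e.g. from [predict_scores()].
#' @param tau_grid Thresholds to sweep.
#' @return A `chunk_eval` tibble with `tau`, `sensitivity`, `specificity`.
#' @export
chunk_metrics <- function(data, tau_grid = seq(0.05, 0.95, by = 0.05)) {
  data <- tibble::as_tibble(data)
  is_pos <- data$label == "polyp"
  if (!any(is_pos) || all(is_pos)) {
    abort(sprintf("undefined metric: ground truth lacks class '%s'",
                  if (!any(is_pos)) "polyp" else "nonpolyp"))
  }
  p <- data$prob_polyp
  out <- purrr::map_dfr(sort(tau_grid), function(tau) {
    flag <- p > tau
    tibble::tibble(tau = tau,
                   sensitivity = mean(flag[is_pos]),
                   specificity = mean(!flag[!is_pos]))
  })
  structure(out, class = c("chunk_eval", class(tibble::tibble())))
}

#' Scene-level evaluation of one clip
#'
#' A clip counts as a correct detection if at least one surviving
#' (post-processed) positive chunk's frame span intersects a ground-truth
#' polyp interval. Maximal positive runs with no polyp overlap are
#' false-positive scenes; their total duration in seconds is the clip's FP
#' load. Intervals are half-open; sharing a single frame counts as overlap.
#'
#' @param keep_labels 0/1 post-processed chunk labels in temporal order.
#' @param gt_scenes Tibble of ground-truth intervals with `start_frame`,
#'   `end_frame`, `label` (only `polyp` rows are used), e.g. from
#'   [scenes_from_annotations()].
#' @param stride,chunk_len,fps Chunk timing metadata.
#' @param clip_frames Total frames in the clip (for the clip duration);
#'   inferred from the chunk count when omitted.
#' @param clip_id Identifier copied into the result.
#' @return One-row tibble: `clip_id`, `detected`, `n_fp_scenes`,
#'   `fp_duration_s`, `clip_duration_s`.
#' @export
evaluate_clip <- function(keep_labels, gt_scenes, stride, chunk_len = 16,
                          fps = 30, clip_frames = NULL, clip_id = "clip") {
  gt <- gt_scenes[gt_scenes$label == "polyp", , drop = FALSE]
  runs <- labels_to_scenes(keep_labels, stride, chunk_len, fps)
  overlaps_gt <- function(s, e) {
    nrow(gt) > 0 && any(pmax(gt$start_frame, s) < pmin(gt$end_frame, e))
  }
  hit <- logical(nrow(runs))
  if (nrow(runs) > 0) {
    hit <- mapply(overlaps_gt, runs$start_frame, runs$end_frame)
  }
  if (is.null(clip_frames)) {
    clip_frames <- (length(keep_labels) - 1) * stride + chunk_len
  }
  tibble::tibble(
    clip_id = clip_id,
    detected = any(hit),
    n_fp_scenes = sum(!hit),
    fp_duration_s = sum(runs$duration_s[!hit]),
    clip_duration_s = clip_frames / fps)
}

#' Aggregate clip results into a scene-level report
#'
#' Detection accuracy is the fraction of clips with a correct detection;
#' the FP statistic is the mean over clips of each clip's total FP-scene
#' duration (the per-event mean duration is also reported as a secondary
#' column).
#'
#' @param clip_results Row-bound [evaluate_clip()] results.
#' @return A `scene_eval` list with `summary` (one-row tibble:
#'   `n_clips`, `detection_accuracy`, `mean_fp_duration_s`,
#'   `mean_fp_event_duration_s`) and `clips`.
#' @export
scene_report <- function(clip_results) {
  if (nrow(clip_results) == 0) abort("no clips to report")
  n_events <- sum(clip_results$n_fp_scenes)
  summary <- tibble::tibble(
    n_clips = nrow(clip_results),
    detection_accuracy = mean(clip_results$detected),
    mean_fp_duration_s = mean(clip_results$fp_duration_s),
    mean_fp_event_duration_s =
      if (n_events > 0) sum(clip_results$fp_duration_s) / n_events else 0)
  structure(list(summary = summary, clips = clip_results),
            class = "scene_eval")
}

#' @export
print.scene_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scene_eval> %d clips: detection accuracy %.2f, mean FP %.2f s/clip\n",
              s$n_clips, s$detection_accuracy, s$mean_fp_duration_s))
  invisible(x)
}

#' @describeIn scene_report One-row summary tibble.
#' @param x A `scene_eval`.
#' @param ... Unused.
#' @export
glance.scene_eval <- function(x, ...) x$summary

#' @describeIn scene_report Per-clip results tibble.
#' @export
tidy.scene_eval <- function(x, ...) x$clips
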