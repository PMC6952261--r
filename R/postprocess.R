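#' Threshold per-chunk polyp probabilities
#'
#' A chunk is flagged iff its polyp probability is *strictly* greater than
#' `tau`.
#'
#' @param scores Numeric vector of polyp-class probabilities in `[0, 1]`.
#' @param tau Decision criterion in `(0, 1)`.
#' @return Integer 0/1 vector of the same length.
#' @export
threshold_flags <- function(scores, tau) {
  if (tau <= 0 || tau >= 1) abort("tau must lie in (0, 1)")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    abort("scores must lie in [0, 1]")
  }
  as.integer(scores > tau)
}

#' Keep only runs of at least N successive flags
#'
#' A flagged chunk survives iff it lies in a maximal run of 1s of length at
#' least `n`. Isolated spikes shorter than `n` are deleted; no new positives
#' are ever created, so the output positives are a subset of the input
#' positives and the filter is idempotent.
#'
#' @param flags Integer 0/1 vector.
#' @param n Minimum run length (`n = 1` is the identity).
#' @return Filtered 0/1 vector.
#' @export
successive_filter <- function(flags, n) {
  if (n < 1) abort("n must be >= 1")
  if (length(flags) == 0) return(integer(0))
  r <- rle(as.integer(flags))
  r$values[r$values == 1 & r$lengths < n] <- 0L
  inverse.rle(r)
}

#' Convert a chunk label sequence to timed scene intervals
#'
#' Chunk `i` (0-based) covers frames `[i*stride, i*stride + chunk_len)`; a
#' maximal run of positive chunks `i..j` maps to the half-open frame interval
#' `[i*stride, j*stride + chunk_len)` with duration `frames / fps` seconds.
#'
#' @param labels 0/1 chunk labels in temporal order.
#' @param stride Frames between successive chunk starts.
#' @param chunk_len Frames per chunk.
#' @param fps Frames per second.
#' @return Tibble with `start_chunk`, `end_chunk` (inclusive), `start_frame`,
#'   `end_frame` (half-open), `duration_s`.
#' @export
labels_to_scenes <- function(labels, stride, chunk_len = 16, fps = 30) {
  labels <- as.integer(labels)
  if (length(labels) == 0 || !any(labels == 1)) {
    return(tibble::tibble(start_chunk = integer(0), end_chunk = integer(0),
                          start_frame = integer(0), end_frame = integer(0),
                          duration_s = numeric(0)))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  pos <- which(r$values == 1)
  i0 <- starts[pos] - 1L  # 0-based first chunk of each run
  j0 <- ends[pos] - 1L    # 0-based last chunk
  tibble::tibble(
    start_chunk = i0, end_chunk = j0,
    start_frame = i0 * stride,
    end_frame = j0 * stride + chunk_len,
    duration_s = (j0 * stride + chunk_len - i0 * stride) / fps)
}

#' Post-process a table of per-chunk scores
#'
#' Data-frame-first wrapper: thresholds and run-filters the polyp
#' probabilities of each video independently and returns the table with
#' `flag` (thresholded) and `keep` (after the N-successive filter) columns.
#'
#' @param data Tibble with columns `video_id`, `chunk_index` (0-based,
#'   consecutive per video) and `polyp_prob`.
#' @param tau Decision threshold.
#' @param n Minimum run length.
#' @return The input tibble plus `flag` and `keep`, ordered by video and
#'   chunk.
#' @export
postprocess_scores <- function(data, tau = 0.5, n = 2) {
  data <- dplyr::arrange(tibble::as_tibble(data), .data$video_id, .data$chunk_index)
  data |>
    dplyr::group_by(.data$video_id) |>
    dplyr::mutate(flag = threshold_flags(.data$polyp_prob, tau),
                  keep = successive_filter(.data$flag, n)) |>
    dplyr::ungroup()
}
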