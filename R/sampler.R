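#' Partition negative chunks into hard and residual pools
#'
#' Negative (non-polyp) chunks from videos flagged as hard-negative sources
#' form the *hard* pool, which every epoch sample retains in full; all other
#' negative chunks form the *residual* pool that is re-subsampled each epoch.
#' Positive chunks never enter either pool.
#'
#' @param chunks A `chunk_set` (or tibble with `chunk_id`, `video_id`,
#'   `label`).
#' @param hard_video_ids Character vector of video ids flagged as
#'   hard-negative.
#' @return A `negative_pool`: list with `hard_ids` and `residual_ids`.
#' @export
partition_negatives <- function(chunks, hard_video_ids = character(0)) {
  chunks <- tibble::as_tibble(chunks)
  unknown <- setdiff(hard_video_ids, unique(chunks$video_id))
  if (length(unknown) > 0) {
    abort(sprintf("hard_video_ids not present in chunk set: %s",
                  paste(unknown, collapse = ", ")))
  }
  neg <- chunks[chunks$label == "nonpolyp", ]
  is_hard <- neg$video_id %in% hard_video_ids
  structure(list(hard_ids = neg$chunk_id[is_hard],
                 residual_ids = neg$chunk_id[!is_hard]),
            class = "negative_pool")
}

#' Draw one epoch's balanced sample
#'
#' Includes every hard-negative chunk, then draws uniformly without
#' replacement from the residual pool until the negative count equals the
#' positive count, so the epoch-level polyp:non-polyp ratio is 1:1. The draw
#' is made on an RNG stream derived from `(base_seed, epoch)`: epochs differ
#' but reruns reproduce exactly. Degenerate regimes warn rather than fail:
#' with more hard negatives than positives all hard negatives are kept (the
#' ratio then exceeds 1:1); with more positives than total negatives all
#' negatives are used.
#'
#' @param pool A [partition_negatives()] result.
#' @param positive_ids Character vector of positive chunk ids.
#' @param epoch Epoch number (1-based).
#' @param base_seed Integer run seed.
#' @return An `epoch_sample`: list with `positive_ids`, `negative_ids`,
#'   `epoch`, `seed`.
#' @export
draw_epoch_sample <- function(pool, positive_ids, epoch, base_seed) {
  stopifnot(inherits(pool, "negative_pool"))
  if (length(positive_ids) == 0) abort("no positive chunks to sample against")
  if (length(pool$hard_ids) + length(pool$residual_ids) == 0) {
    abort("negative pool is empty")
  }
  n_pos <- length(positive_ids)
  n_hard <- length(pool$hard_ids)
  n_res <- length(pool$residual_ids)
  n_draw <- max(0L, n_pos - n_hard)
  if (n_hard > n_pos) {
    warn(sprintf(
      "hard-negative pool (%d) exceeds positive count (%d); keeping all hard negatives, ratio exceeds 1:1",
      n_hard, n_pos))
  }
  if (n_pos > n_hard + n_res) {
    warn(sprintf(
      "positives (%d) exceed total negatives (%d); using all negatives",
      n_pos, n_hard + n_res))
    n_draw <- n_res
  }
  seed <- derive_seed(base_seed, epoch)
  drawn <- if (n_draw > 0) {
    with_seed(seed, sample(pool$residual_ids, min(n_draw, n_res)))
  } else character(0)
  structure(list(positive_ids = positive_ids,
                 negative_ids = c(pool$hard_ids, drawn),
                 epoch = as.integer(epoch), seed = seed),
            class = "epoch_sample")
}

#' Epoch sample as an audit manifest
#'
#' @param sample An `epoch_sample`.
#' @param pool The pool it was drawn from (to mark hard negatives).
#' @return Tibble with `epoch`, `chunk_id`, `label`, `is_hard`.
#' @export
epoch_sample_manifest <- function(sample, pool) {
  tibble::tibble(
    epoch = sample$epoch,
    chunk_id = c(sample$positive_ids, sample$negative_ids),
    label = rep(c("polyp", "nonpolyp"),
                c(length(sample$positive_ids), length(sample$negative_ids))),
    is_hard = c(rep(FALSE, length(sample$positive_ids)),
                sample$negative_ids %in% pool$hard_ids))
}

#' Balanced class weights
#'
#' For class counts \eqn{N_k} out of \eqn{N} training samples over \eqn{K}
#' classes, the balanced weight is \eqn{w_k = N / (K N_k)}, so that
#' \eqn{\sum_k w_k N_k = N} exactly and equal counts give unit weights.
#'
#' @param counts Named integer vector of per-class sample counts (all > 0).
#' @return A `class_weights` tibble with columns `class`, `n`, `weight` and
#'   attributes `N` (total) and `K` (number of classes).
#' @export
class_weights <- function(counts) {
  if (any(counts <= 0)) {
    abort(sprintf("undefined weight: zero count for class %s",
                  paste(names(counts)[counts <= 0], collapse = ", ")))
  }
  N <- sum(counts)
  K <- length(counts)
  out <- tibble::tibble(class = names(counts) %||% as.character(seq_len(K)),
                        n = as.numeric(counts),
                        weight = N / (K * as.numeric(counts)))
  structure(out, N = N, K = K,
            class = c("class_weights", class(tibble::tibble())))
}
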