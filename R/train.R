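#' Weighted cross-entropy
#'
#' Batch loss \eqn{H_w(P, Q) = -\sum_k \sum_{n_k} w_k P(l | x) \log Q(l |
#' f(x))} with ground truth `p` one-hot and balanced class weights
#' \eqn{w_k = N/(K N_k)}. With all weights 1 it reduces to the standard
#' cross-entropy sum. Probabilities are clamped at `1e-12` inside the log.
#'
#' @param p One-hot ground-truth matrix (samples x classes) or vector.
#' @param q Predicted probability matrix/vector of the same shape.
#' @param w Per-class weights: numeric vector or a [class_weights()] tibble.
#' @return The summed weighted cross-entropy over the batch.
#' @export
weighted_cross_entropy <- function(p, q, w = NULL) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (is.vector(q)) q <- matrix(q, nrow = 1)
  stopifnot(identical(dim(p), dim(q)))
  if (any(q < -1e-9 | q > 1 + 1e-9) ||
      any(abs(rowSums(q) - 1) > 1e-6)) {
    abort("q must be valid probability rows summing to 1")
  }
  K <- ncol(p)
  if (is.null(w)) w <- rep(1, K)
  if (inherits(w, "class_weights")) w <- w$weight
  stopifnot(length(w) == K)
  wk <- matrix(w, nrow(p), K, byrow = TRUE)
  -sum(wk * p * log(pmax(q, 1e-12)))
}

#' Training configuration
#'
#' Defaults follow the published settings: Adam, learning rate `1e-5` for 30
#' epochs for the C3D-like baseline and `1e-6` for 70 epochs for the
#' residual networks (those rates suit the full-size dataset; desk-scale
#' runs on synthetic data typically pass larger rates and fewer epochs).
#' `NULL` learning rate/epochs are resolved from the model at [train()]
#' time. Batch size is not pinned by the published settings; 32 is the
#' package default.
#'
#' @param balancing `"subsample"` (epoch-wise 1:1 negative subsampling with
#'   hard-negative retention), `"class_weight"` (balanced-weight loss over
#'   all chunks), or `"none"` (plain cross-entropy over all chunks).
#' @param learning_rate,epochs Optimizer settings (`NULL` = model default).
#' @param batch_size Chunks per gradient step.
#' @param seed Run seed; fixes subsampling, shuffling, dropout and therefore
#'   the whole loss trajectory.
#' @param early_stopping Optional patience in epochs on validation accuracy.
#' @param stop_accuracy Optional target validation accuracy; training stops
#'   once an epoch reaches it.
#' @param keep_checkpoints `"all"` or `"best"`.
#' @return A `train_config` list.
#' @export
train_config <- function(balancing = c("subsample", "class_weight", "none"),
                         learning_rate = NULL, epochs = NULL, batch_size = 32,
                         seed = 1, early_stopping = NULL, stop_accuracy = NULL,
                         keep_checkpoints = "all") {
  balancing <- match.arg(balancing)
  if (!is.null(learning_rate) && learning_rate <= 0) abort("learning_rate must be > 0")
  if (!is.null(epochs) && epochs < 1) abort("epochs must be >= 1")
  structure(list(optimizer = "adam", balancing = balancing,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = seed,
                 early_stopping = early_stopping, stop_accuracy = stop_accuracy,
                 keep_checkpoints = keep_checkpoints, augment = NULL),
            class = "train_config")
}

resolve_config <- function(config, spec) {
  if (is.null(config$learning_rate)) {
    config$learning_rate <- if (spec$kind == "c3d") 1e-5 else 1e-6
  }
  if (is.null(config$epochs)) {
    config$epochs <- if (spec$kind == "c3d") 30L else 70L
  }
  config
}

label_int <- function(label) ifelse(label == "polyp", 1L, 2L)

#' Train a polyp-scene classifier
#'
#' One gradient pass per batch with Adam; per-epoch validation accuracy,
#' sensitivity and specificity (at probability threshold 0.5) are logged and
#' a checkpoint is kept per epoch. In `subsample` mode each epoch iterates
#' exactly the epoch's balanced sample (all positives, all hard negatives,
#' a fresh uniform residual draw) with unit loss weights; in `class_weight`
#' mode each epoch iterates every chunk with balanced weights computed from
#' the full training counts; `none` iterates every chunk unweighted. The
#' loss is logged as a per-sample mean so curves are comparable across batch
#' sizes (the summed form defines gradients up to that constant). Runs are
#' fully determined by `config$seed`.
#'
#' @param model A [build_model()] result.
#' @param train_chunks,val_chunks `chunk_set`s with disjoint patients.
#' @param config A [train_config()].
#' @param pool A [partition_negatives()] pool (required for `subsample`).
#' @return A `polyp_fit` with elements `model` (best-checkpoint weights
#'   loaded), `checkpoints`, `logs`, `config`, `best`.
#' @export
train <- function(model, train_chunks, val_chunks, config = train_config(),
                  pool = NULL) {
  stopifnot(inherits(model, "polyp_model"))
  config <- resolve_config(config, model$spec)
  if (nrow(train_chunks) == 0 || nrow(val_chunks) == 0) {
    abort("empty train or validation split")
  }
  if (config$balancing == "subsample" && is.null(pool)) {
    abort("subsample balancing requires a negative pool")
  }
  meta <- tibble::as_tibble(train_chunks)
  row_of <- setNames(seq_len(nrow(meta)), meta$chunk_id)
  positive_ids <- meta$chunk_id[meta$label == "polyp"]

  class_w <- c(1, 1)
  if (config$balancing == "class_weight") {
    counts <- c(polyp = sum(meta$label == "polyp"),
                nonpolyp = sum(meta$label == "nonpolyp"))
    cw <- class_weights(counts)
    class_w <- cw$weight[match(c("polyp", "nonpolyp"), cw$class)]
  }

  wd <- model$spec$weight_decay
  lr <- config$learning_rate
  m_adam <- numeric(length(model$params))
  v_adam <- numeric(length(model$params))
  t_adam <- 0
  logs <- list()
  checkpoints <- list()
  best_acc <- -Inf
  best_epoch <- 0L

  for (epoch in seq_len(config$epochs)) {
    if (config$balancing == "subsample") {
      es <- draw_epoch_sample(pool, positive_ids, epoch, config$seed)
      ids <- c(es$positive_ids, es$negative_ids)
    } else {
      ids <- meta$chunk_id
    }
    ids <- with_seed(derive_seed(config$seed, epoch, 7L), sample(ids))
    rows <- row_of[ids]

    loss_sum <- 0
    n_seen <- 0
    n_batches <- ceiling(length(rows) / config$batch_size)
    for (b in seq_len(n_batches)) {
      idx <- rows[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                        length(rows))]
      r <- forward_batch(model, meta$tensor[idx],
                         training = TRUE, labels = label_int(meta$label[idx]),
                         class_w = class_w, want_grad = TRUE,
                         dropout_seed = derive_seed(config$seed, epoch, b, 13L))
      if (!is.finite(r$loss)) {
        abort(sprintf("divergent loss (%s) at epoch %d batch %d; try a smaller learning rate",
                      r$loss, epoch, b))
      }
      g <- r$grad + wd * model$decay_mask * model$params
      t_adam <- t_adam + 1
      m_adam <- 0.9 * m_adam + 0.1 * g
      v_adam <- 0.999 * v_adam + 0.001 * g^2
      mhat <- m_adam / (1 - 0.9^t_adam)
      vhat <- v_adam / (1 - 0.999^t_adam)
      model$params <- model$params - lr * mhat / (sqrt(vhat) + 1e-8)
      model$buffers <- r$buffers
      loss_sum <- loss_sum + r$loss
      n_seen <- n_seen + length(idx)
    }

    val <- predict_scores(model, val_chunks)
    pred_pos <- val$prob_polyp > 0.5
    is_pos <- val$label == "polyp"
    acc <- mean(pred_pos == is_pos)
    sens <- if (any(is_pos)) mean(pred_pos[is_pos]) else NA_real_
    spc <- if (any(!is_pos)) mean(!pred_pos[!is_pos]) else NA_real_
    logs[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = loss_sum / n_seen, n_train = n_seen,
      validation_accuracy = acc, validation_sensitivity = sens,
      validation_specificity = spc)
    ckpt <- list(epoch = epoch, params = model$params, buffers = model$buffers,
                 validation_accuracy = acc,
                 sidecar = list(model_id = model$spec$model_id,
                                width_scale = model$spec$width_scale,
                                seed = config$seed, epoch = epoch,
                                validation_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_epoch <- epoch
    }
    if (identical(config$keep_checkpoints, "best")) {
      if (epoch == best_epoch) checkpoints[[1]] <- ckpt
    } else {
      checkpoints[[epoch]] <- ckpt
    }
    if (!is.null(config$stop_accuracy) && acc >= config$stop_accuracy) break
    if (!is.null(config$early_stopping) &&
        epoch - best_epoch >= config$early_stopping) break
  }

  logs <- dplyr::bind_rows(logs)
  fit <- structure(list(model = model, checkpoints = checkpoints, logs = logs,
                        config = config), class = "polyp_fit")
  fit$best <- select_best(fit)
  fit$model <- load_checkpoint(model, fit$best)
  fit
}

#' Select the best checkpoint by validation accuracy
#'
#' Ties resolve to the earliest epoch.
#'
#' @param checkpoints A `polyp_fit` or a list of checkpoints.
#' @param logs Optional epoch-log tibble (unused when a fit is given).
#' @return The winning checkpoint.
#' @export
select_best <- function(checkpoints, logs = NULL) {
  if (inherits(checkpoints, "polyp_fit")) checkpoints <- checkpoints$checkpoints
  if (length(checkpoints) == 0) abort("no checkpoints")
  acc <- vapply(checkpoints, function(c) c$validation_accuracy, numeric(1))
  checkpoints[[which.max(acc)]]
}

#' Load checkpoint weights into a model
#'
#' @param model A `polyp_model`.
#' @param checkpoint A checkpoint from [train()].
#' @return The model with the checkpoint's parameters and buffers.
#' @export
load_checkpoint <- function(model, checkpoint) {
  model$params <- checkpoint$params
  model$buffers <- checkpoint$buffers
  model
}

#' Save a checkpoint with a JSON sidecar
#'
#' Writes the weights in R native serialization and the sidecar (model id,
#' width scale, seed, epoch, validation accuracy) as `<path>.json`.
#'
#' @param checkpoint A checkpoint from [train()].
#' @param path Output file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  jsonlite::write_json(checkpoint$sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.polyp_fit <- function(x, ...) {
  cat(sprintf("<polyp_fit> %s, balancing=%s, %d epoch(s), best val acc %.3f (epoch %d)\n",
              x$model$spec$model_id, x$config$balancing, nrow(x$logs),
              x$best$validation_accuracy, x$best$epoch))
  invisible(x)
}

#' @describeIn train Epoch logs as a tibble.
#' @param x A `polyp_fit`.
#' @param ... Unused.
#' @export
tidy.polyp_fit <- function(x, ...) x$logs

#' @describeIn train One-row training summary.
#' @export
glance.polyp_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model$spec$model_id,
    balancing = x$config$balancing,
    epochs = nrow(x$logs),
    best_epoch = x$best$epoch,
    best_validation_accuracy = x$best$validation_accuracy,
    final_train_loss = x$logs$train_loss[nrow(x$logs)])
}
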