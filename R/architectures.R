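#' 3D network architecture presets
#'
#' Builds the stage description of the four 3D ResNet variants used for
#' polyp-scene classification, plus a configurable C3D-like plain 3D CNN
#' baseline. All residual stages use 3x3x3 kernels with two convolutions per
#' residual unit (conv, batch norm, ReLU, conv, batch norm, shortcut
#' addition, ReLU). Model I uses a width-32 stem and pool stride 1x2x2 with
#' five residual stages (widths 32, 64, 128, 256, 512); models II-IV use a
#' width-64 stem and pool stride 2x2x2 with stage widths (64, 128, 256, 512),
#' (64, 128, 256, 512) and (128, 256, 512) respectively, the wide variants
#' doubling the narrow ones' stage widths. Spatial/temporal downsampling is
#' a stride-2x2x2 first convolution at each stage transition after the first,
#' with a 1x1x1 projection shortcut whenever shape changes.
#'
#' @param model One of `"I"`, `"II"`, `"III"`, `"IV"`, `"c3d_like"`.
#' @param width_scale Multiplier applied to every channel width (and the
#'   C3D-like fully-connected width); fractional values give desk-scale test
#'   variants with identical topology.
#' @param num_classes Output classes (default 2: polyp, nonpolyp).
#' @param fc_width Width of the two fully-connected layers of the C3D-like
#'   baseline (before scaling).
#' @return An `arch_spec` list.
#' @export
resnet3d_spec <- function(model = c("I", "II", "III", "IV", "c3d_like"),
                          width_scale = 1, num_classes = 2, fc_width = 2048) {
  model <- match.arg(model)
  sw <- function(w) pmax(1L, as.integer(round(w * width_scale)))
  presets <- list(
    I   = list(conv1 = 32, pool = c(1, 2, 2), widths = c(32, 64, 128, 256, 512)),
    II  = list(conv1 = 64, pool = c(2, 2, 2), widths = c(64, 128, 256, 512)),
    III = list(conv1 = 64, pool = c(2, 2, 2), widths = c(64, 128, 256, 512)),
    IV  = list(conv1 = 64, pool = c(2, 2, 2), widths = c(128, 256, 512)))
  if (model == "c3d_like") {
    spec <- list(model_id = model, kind = "c3d",
                 conv_widths = sw(c(64, 128, 256, 256, 512)),
                 fc_width = sw(fc_width), dropout = 0.5,
                 num_classes = num_classes, weight_decay = 1e-4,
                 width_scale = width_scale)
  } else {
    p <- presets[[model]]
    widths <- sw(p$widths)
    spec <- list(model_id = model, kind = "resnet",
                 conv1_width = sw(p$conv1), pool_stride = p$pool,
                 stages = tibble::tibble(
                   name = paste0("conv", seq_along(widths) + 1),
                   width = widths,
                   kernel = "3x3x3",
                   units = 1L,
                   downsample = c(FALSE, rep(TRUE, length(widths) - 1))),
                 num_classes = num_classes, weight_decay = 1e-4,
                 width_scale = width_scale)
  }
  structure(spec, class = "arch_spec")
}

# Lower an arch_spec to the engine op list, assigning parameter and buffer
# offsets. Returns ops, parameter/buffer sizes and a layout table used for
# initialization and the weight-decay mask.
build_ops <- function(spec, input_dim = c(16, 112, 112)) {
  env <- new.env()
  env$ops <- list()
  env$off <- 0
  env$boff <- 0
  env$layout <- list()
  env$dim <- input_dim  # (T, H, W)
  env$cin <- 3L

  lay <- function(kind, offset, length, fan_in = NA_real_, decay = FALSE) {
    env$layout[[length(env$layout) + 1]] <-
      tibble::tibble(kind = kind, offset = offset, length = length,
                     fan_in = fan_in, decay = decay)
  }
  conv_fields <- function(cin, cout, k, s, p) {
    wlen <- prod(k) * cin * cout
    woff <- env$off
    boff <- env$off + wlen
    lay("conv_w", woff, wlen, fan_in = prod(k) * cin, decay = TRUE)
    lay("conv_b", boff, cout)
    env$off <- env$off + wlen + cout
    list(kt = k[1], kh = k[2], kw = k[3], st = s[1], sh = s[2], sw = s[3],
         pt = p[1], ph = p[2], pw = p[3], cin = cin, cout = cout,
         woff = woff, boff = boff)
  }
  bn_fields <- function(c) {
    goff <- env$off
    lay("bn_gamma", goff, c)
    lay("bn_beta", goff + c, c)
    env$off <- env$off + 2 * c
    f <- list(c = c, goff = goff, betaoff = goff + c,
              rmoff = env$boff, rvoff = env$boff + c)
    env$boff <- env$boff + 2 * c
    f
  }
  add <- function(op) env$ops[[length(env$ops) + 1]] <- op
  conv_out <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1

  add_conv <- function(cout, k = c(3, 3, 3), s = c(1, 1, 1), p = c(1, 1, 1)) {
    add(c(list(type = "conv"), conv_fields(env$cin, cout, k, s, p)))
    env$dim <- mapply(conv_out, env$dim, k, s, p)
    env$cin <- cout
  }
  add_bn <- function() add(c(list(type = "bn"), bn_fields(env$cin)))
  add_relu <- function() add(list(type = "relu"))
  add_pool <- function(k, s = k) {
    add(list(type = "pool", kt = k[1], kh = k[2], kw = k[3],
             st = s[1], sh = s[2], sw = s[3]))
    env$dim <- mapply(function(n, kk, ss) floor((n - kk) / ss) + 1, env$dim, k, s)
  }
  add_fc <- function(cout) {
    cin <- env$cin
    woff <- env$off
    lay("fc_w", woff, cin * cout, fan_in = cin)
    lay("fc_b", woff + cin * cout, cout)
    env$off <- env$off + cin * cout + cout
    add(list(type = "fc", cin = cin, cout = cout, woff = woff,
             boff = woff + cin * cout))
    env$cin <- cout
    env$dim <- c(1, 1, 1)
  }

  if (spec$kind == "resnet") {
    add_conv(spec$conv1_width)
    add_bn(); add_relu()
    add_pool(spec$pool_stride)
    for (i in seq_len(nrow(spec$stages))) {
      w <- spec$stages$width[i]
      s <- if (spec$stages$downsample[i]) c(2, 2, 2) else c(1, 1, 1)
      cin <- env$cin
      in_dim <- env$dim
      add(list(type = "push"))
      add_conv(w, s = s)
      add_bn(); add_relu()
      add_conv(w)
      add_bn()
      if (any(s != 1) || cin != w) {
        f <- conv_fields(cin, w, k = c(1, 1, 1), s = s, p = c(0, 0, 0))
        b <- bn_fields(w)
        add(c(list(type = "addproj"), f, b))
      } else {
        add(list(type = "addid"))
      }
      add_relu()
      rm(in_dim)
    }
    add(list(type = "gap"))
    env$dim <- c(1, 1, 1)
    add_fc(spec$num_classes)
  } else {
    pools <- list(c(1, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2))
    for (j in seq_along(spec$conv_widths)) {
      add_conv(spec$conv_widths[j])
      add_bn(); add_relu()
      add_pool(pools[[j]])
    }
    flat <- env$cin * prod(env$dim)
    add(list(type = "flatten"))
    env$cin <- as.integer(flat)
    env$dim <- c(1, 1, 1)
    add_fc(spec$fc_width); add_relu(); add(list(type = "dropout", rate = spec$dropout))
    add_fc(spec$fc_width); add_relu(); add(list(type = "dropout", rate = spec$dropout))
    add_fc(spec$num_classes)
  }

  list(ops = env$ops, n_params = env$off, n_buffers = env$boff,
       layout = dplyr::bind_rows(env$layout))
}

#' Build a model from an architecture spec
#'
#' Allocates and initializes all trainable parameters (He-normal
#' convolution/affine kernels, zero biases, unit-gamma/zero-beta batch norm)
#' and the batch-norm running statistics. The forward pass maps a batch of
#' `16 x 112 x 112 x 3` chunks to per-class scores; weight decay 1e-4 is
#' applied to convolution kernels during training.
#'
#' @param spec An [resnet3d_spec()] result.
#' @param num_classes Overrides the spec's class count if given.
#' @param seed Seed for parameter initialization.
#' @param input_dim Input chunk geometry `(T, H, W)`; the classification
#'   convention is `c(16, 112, 112)`.
#' @return A `polyp_model`.
#' @export
build_model <- function(spec, num_classes = NULL, seed = 1,
                        input_dim = c(16, 112, 112)) {
  stopifnot(inherits(spec, "arch_spec"))
  if (!is.null(num_classes)) spec$num_classes <- num_classes
  built <- build_ops(spec, input_dim = input_dim)
  params <- numeric(built$n_params)
  decay_mask <- numeric(built$n_params)
  with_seed(seed, {
    for (i in seq_len(nrow(built$layout))) {
      row <- built$layout[i, ]
      idx <- row$offset + seq_len(row$length)
      params[idx] <- switch(row$kind,
        conv_w = rnorm(row$length, 0, sqrt(2 / row$fan_in)),
        fc_w = rnorm(row$length, 0, sqrt(2 / row$fan_in)),
        bn_gamma = 1,
        0)
      if (isTRUE(row$decay)) decay_mask[idx] <- 1
    }
  })
  buffers <- numeric(built$n_buffers)
  # running variances start at 1
  for (op in built$ops) {
    if (op$type %in% c("bn", "addproj")) {
      buffers[op$rvoff + seq_len(op$c)] <- 1
    }
  }
  structure(list(spec = spec, ops = built$ops, layout = built$layout,
                 params = params, buffers = buffers, decay_mask = decay_mask,
                 input_dim = c(as.integer(input_dim), 3L), seed = seed),
            class = "polyp_model")
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution and affine kernels and biases,
#' and batch-norm scale/shift pairs (running statistics are buffers, not
#' parameters).
#'
#' @param x A `polyp_model` or `arch_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "polyp_model")) return(length(x$params))
  if (inherits(x, "arch_spec")) return(build_ops(x)$n_params)
  abort("count_parameters expects a polyp_model or arch_spec")
}

#' @export
print.polyp_model <- function(x, ...) {
  cat(sprintf("<polyp_model %s> width_scale=%g, %s trainable parameters\n",
              x$spec$model_id, x$spec$width_scale,
              format(length(x$params), big.mark = ",")))
  invisible(x)
}

#' Numerically stable softmax
#'
#' \eqn{q_l = e^{y_l} / \sum_k e^{y_k}}, computed after subtracting the row
#' maximum. Rows of a matrix are treated as independent score vectors.
#'
#' @param y Numeric vector of class scores, or a matrix with one score vector
#'   per row.
#' @return Probabilities of the same shape, each (row) summing to 1.
#' @export
softmax <- function(y) {
  if (!all(is.finite(y))) abort("softmax requires finite scores")
  if (is.matrix(y)) {
    z <- exp(y - apply(y, 1, max))
    z / rowSums(z)
  } else {
    z <- exp(y - max(y))
    z / sum(z)
  }
}

# Concatenate chunk tensors into one raw batch and run the engine.
forward_batch <- function(model, tensors, training = FALSE,
                          labels = NULL, class_w = c(1, 1), want_grad = FALSE,
                          dropout_seed = 0L) {
  expected <- prod(model$input_dim)
  lens <- lengths(tensors)
  if (any(lens != expected)) {
    abort(sprintf("input shape mismatch: expected chunks of shape (%s)",
                  paste(model$input_dim, collapse = ",")))
  }
  x <- unlist(tensors, use.names = FALSE)
  if (!is.raw(x)) x <- as.raw(x)
  B <- length(tensors)
  d <- model$input_dim
  nn_run(model$params, model$buffers, model$ops, x,
         c(B, 3L, d[1], d[2], d[3]), training,
         if (is.null(labels)) integer(0) else as.integer(labels),
         as.numeric(class_w), want_grad, as.integer(dropout_seed))
}

#' Score chunks with a model
#'
#' Runs the model in evaluation mode (batch norm uses running statistics) and
#' returns per-chunk class scores and the polyp softmax probability.
#'
#' @param model A `polyp_model`.
#' @param chunks A `chunk_set`.
#' @param batch_size Chunks per forward batch.
#' @return The chunk metadata tibble plus `score_polyp`, `score_nonpolyp`,
#'   `prob_polyp`.
#' @export
predict_scores <- function(model, chunks, batch_size = 16) {
  n <- nrow(chunks)
  scores <- matrix(NA_real_, n, model$spec$num_classes)
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    r <- forward_batch(model, chunks$tensor[idx])
    scores[idx, ] <- r$scores
  }
  probs <- softmax(scores)
  out <- tibble::as_tibble(chunks)[, c("chunk_id", "video_id", "start_frame", "label")]
  out$score_polyp <- scores[, 1]
  out$score_nonpolyp <- scores[, 2]
  out$prob_polyp <- probs[, 1]
  out
}
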