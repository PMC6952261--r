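#' Synthetic colonoscopy video configuration
#'
#' Defaults mirror the structure of the clinical recordings the toolkit is
#' aimed at: 30 fps clips of 50-60 s, polyp scenes of 2-10 s, a chunk-level
#' polyp:non-polyp imbalance near 1:3.16, and a fifth of the non-polyp
#' videos flagged as hard-negative sources (near-wall close-ups). Frames are
#' rendered at 112 x 112 directly; `render_size = 448` renders large frames
#' to exercise the resize path instead.
#'
#' @param n_videos Number of videos.
#' @param fps Frames per second.
#' @param duration_s Length-2 range of clip durations in seconds.
#' @param scene_len_s Length-2 range of polyp-scene durations in seconds.
#' @param frame_size Stored frame side length.
#' @param render_size Optional larger rendering resolution.
#' @param blob_radius Length-2 range of polyp blob radii in pixels (at the
#'   112-pixel scale).
#' @param blob_contrast Additive intensity contrast of the blob; the single
#'   difficulty knob.
#' @param blob_drift Blob drift speed in pixels/frame.
#' @param blur_rate Fraction of frames receiving motion-blur noise.
#' @param bubble_rate Bubble events per second.
#' @param specular_rate Specular-spot events per second.
#' @param hard_negative_fraction Fraction of non-polyp videos flagged as
#'   hard-negative sources.
#' @param polyp_video_fraction Fraction of videos containing polyp scenes.
#' @param target_imbalance Target non-polyp chunks per polyp chunk
#'   (default 3.16).
#' @param chunk_len,overlap Chunking convention used for the imbalance
#'   accounting.
#' @param split_fractions Named train/validation/test fractions.
#' @param seed Dataset seed; determines every video seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_videos = 12, fps = 30, duration_s = c(50, 60),
                         scene_len_s = c(2, 10), frame_size = 112,
                         render_size = NULL, blob_radius = c(10, 18),
                         blob_contrast = 0.35, blob_drift = 0.4,
                         blur_rate = 0.02, bubble_rate = 0.02,
                         specular_rate = 0.05, hard_negative_fraction = 0.2,
                         polyp_video_fraction = 0.5, target_imbalance = 3.16,
                         chunk_len = 16, overlap = 8,
                         split_fractions = c(train = 0.6, validation = 0.2,
                                             test = 0.2),
                         seed = 1) {
  stopifnot(length(duration_s) == 2, length(scene_len_s) == 2,
            diff(duration_s) >= 0, diff(scene_len_s) >= 0)
  if (scene_len_s[1] > duration_s[2]) {
    abort("infeasible config: polyp scene longer than the video")
  }
  rates <- c(blur_rate, bubble_rate, specular_rate)
  if (any(rates < 0)) abort("noise rates must be >= 0")
  structure(as.list(environment()), class = "synth_config")
}

# --- small image helpers (vectorized matrix ops) -------------------------

# One-dimensional box blur along rows, replicate padding.
box1d <- function(m, k) {
  n <- nrow(m)
  pad <- rbind(m[rep(1, k), , drop = FALSE], m, m[rep(n, k), , drop = FALSE])
  cs <- apply(pad, 2, cumsum)
  (cs[(2 * k + 1):(2 * k + n), , drop = FALSE] - cs[1:n, , drop = FALSE]) / (2 * k)
}

# Separable box blur (approximate Gaussian after `passes` repeats).
blur_mat <- function(m, k = 3, passes = 2) {
  for (i in seq_len(passes)) m <- t(box1d(t(box1d(m, k)), k))
  m
}

# Bilinear sample of a big field S at window origin (oy, ox) with pixel step
# `scale` (scale < 1 magnifies the texture).
sample_window <- function(S, oy, ox, res, scale = 1) {
  ys <- oy + (seq_len(res) - 1) * scale
  xs <- ox + (seq_len(res) - 1) * scale
  ys <- pmin(pmax(ys, 1), nrow(S) - 1e-6)
  xs <- pmin(pmax(xs, 1), ncol(S) - 1e-6)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  a <- S[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))]
  b <- S[cbind(rep(y0, length(x0)), rep(x0 + 1, each = length(y0)))]
  d <- S[cbind(rep(y0 + 1, length(x0)), rep(x0, each = length(y0)))]
  e <- S[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
  wfy <- rep(fy, length(x0)); wfx <- rep(fx, each = length(y0))
  v <- (a * (1 - wfx) + b * wfx) * (1 - wfy) + (d * (1 - wfx) + e * wfx) * wfy
  matrix(v, res, res)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Pack polyp scenes of random length into a video until `target_frames` of
# polyp coverage is reached; returns half-open frame intervals.
place_scenes <- function(F, fps, scene_len_s, target_frames, min_gap = 8L) {
  min_len <- round(scene_len_s[1] * fps)
  lens <- integer(0)
  while (sum(lens) < target_frames && length(lens) <= 200) {
    l <- round(runif(1, scene_len_s[1], scene_len_s[2]) * fps)
    remaining <- target_frames - sum(lens)
    if (l > remaining) {
      # final scene: land as close to the target as the length range allows
      if (remaining >= min_len) {
        l <- remaining
      } else if (remaining > min_len / 2) {
        l <- min_len
      } else {
        break
      }
    }
    lens <- c(lens, as.integer(l))
  }
  # trim any overshoot from the longest scenes (never below the minimum
  # length) so the realized coverage matches the target exactly when possible
  excess <- sum(lens) - target_frames
  for (j in order(lens, decreasing = TRUE)) {
    if (excess <= 0) break
    cut <- min(excess, lens[j] - min_len)
    lens[j] <- lens[j] - cut
    excess <- excess - cut
  }
  n <- length(lens)
  if (n == 0) return(tibble::tibble(start_frame = integer(0), end_frame = integer(0)))
  total_gap <- F - sum(lens) - (n + 1) * min_gap
  if (total_gap < 0) {
    abort("infeasible config: polyp scenes do not fit in the video")
  }
  cuts <- sort(runif(n, 0, total_gap))
  gaps <- diff(c(0, cuts, total_gap)) + min_gap
  starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(lens))[seq_len(n)]
  tibble::tibble(start_frame = as.integer(round(starts)),
                 end_frame = as.integer(round(starts)) + lens)
}

#' Generate one synthetic colonoscopy-like video
#'
#' The background is a low-frequency drifting wall texture; polyp scenes
#' render a persistent bright elliptical blob with soft edges, a specular
#' highlight and slow drift (temporal coherence across the scene);
#' hard-negative intervals render magnified, low-motion near-wall close-ups
#' without a blob; noise frames receive motion blur, bright bubble circles
#' or saturated specular spots. Output is byte-identical for identical
#' seeds.
#'
#' @param config A [synth_config()].
#' @param video_seed Integer seed for this video.
#' @param video_id,patient_id Identifiers.
#' @param kind `"polyp"`, `"nonpolyp"` or `"hard_negative"` (a non-polyp
#'   video with close-up intervals, flagged as a hard-negative source).
#' @param duration_s Clip length in seconds (drawn from the config range
#'   when omitted).
#' @param polyp_coverage Fraction of frames inside polyp scenes for
#'   `"polyp"` videos.
#' @param polyp_scenes Optional explicit scene plan (tibble with
#'   `start_frame`, `end_frame`, half-open) overriding the drawn placement.
#' @param split Dataset split tag copied into the record.
#' @return A `synth_video`: list with `record` (a [video_record()]) and
#'   `provenance` (scene, noise and close-up event tables).
#' @export
generate_video <- function(config, video_seed, video_id = "v001",
                           patient_id = video_id,
                           kind = c("polyp", "nonpolyp", "hard_negative"),
                           duration_s = NULL, polyp_coverage = 0.4,
                           polyp_scenes = NULL, split = NA_character_) {
  kind <- match.arg(kind)
  res <- config$render_size %||% config$frame_size
  scale_px <- res / 112  # blob sizes are specified at the 112-pixel scale
  with_seed(video_seed, {
    if (is.null(duration_s)) {
      duration_s <- runif(1, config$duration_s[1], config$duration_s[2])
    }
    F <- as.integer(round(duration_s * config$fps))
    if (kind == "polyp" && is.null(polyp_scenes) &&
        round(config$scene_len_s[1] * config$fps) > F) {
      abort("infeasible config: polyp scene longer than the video")
    }

    marg <- ceiling(60 * scale_px)
    S <- matrix(runif((res + marg) * (res + marg), -1, 1), res + marg)
    S <- blur_mat(S, k = max(3, round(5 * scale_px)), passes = 3)
    S <- S / max(abs(S))

    # smooth drifting viewpoint
    oy <- 1 + marg / 2 + cumsum(rnorm(F, 0, 0.25 * scale_px))
    ox <- 1 + marg / 2 + cumsum(rnorm(F, 0, 0.25 * scale_px))
    oy <- pmin(pmax(oy, 1), marg); ox <- pmin(pmax(ox, 1), marg)

    if (is.null(polyp_scenes)) {
      polyp_scenes <- tibble::tibble(start_frame = integer(0), end_frame = integer(0))
      if (kind == "polyp") {
        polyp_scenes <- place_scenes(F, config$fps, config$scene_len_s,
                                     target_frames = round(polyp_coverage * F))
        polyp_scenes <- polyp_scenes[polyp_scenes$end_frame <= F, , drop = FALSE]
      }
    } else {
      polyp_scenes <- tibble::as_tibble(polyp_scenes)
      if (nrow(polyp_scenes) > 0 && max(polyp_scenes$end_frame) > F) {
        abort("infeasible config: polyp scene extends past the video")
      }
    }
    hard_intervals <- tibble::tibble(start_frame = integer(0), end_frame = integer(0))
    if (kind == "hard_negative") {
      n_cu <- sample(1:3, 1)
      cu_len <- round(runif(n_cu, 3, 8) * config$fps)
      cu_start <- sort(sample.int(max(1, F - max(cu_len)), n_cu))
      hard_intervals <- tibble::tibble(
        start_frame = as.integer(cu_start),
        end_frame = as.integer(pmin(cu_start + cu_len, F)))
    }
    in_interval <- function(f, iv) {
      nrow(iv) > 0 && any(f >= iv$start_frame & f < iv$end_frame)
    }

    # per-scene blob trajectories (drawn up front for coherence)
    blob <- NULL
    if (nrow(polyp_scenes) > 0) {
      blob <- lapply(seq_len(nrow(polyp_scenes)), function(i) {
        L <- polyp_scenes$end_frame[i] - polyp_scenes$start_frame[i]
        list(cy = clamp01(0.5 + cumsum(rnorm(L, 0, config$blob_drift / 112)) / 4) * res,
             cx = clamp01(0.5 + cumsum(rnorm(L, 0, config$blob_drift / 112)) / 4) * res,
             rx = runif(1, config$blob_radius[1], config$blob_radius[2]) * scale_px,
             ry = runif(1, config$blob_radius[1], config$blob_radius[2]) * scale_px,
             th = runif(1, 0, pi))
      })
    }

    blur_frames <- which(runif(F) < config$blur_rate)
    n_bub <- rpois(1, config$bubble_rate * duration_s)
    bubble_frames <- integer(0)
    bubbles <- list()
    if (n_bub > 0) {
      for (i in seq_len(n_bub)) {
        f0 <- sample.int(F, 1)
        fr <- f0:min(F, f0 + sample(2:6, 1) - 1)
        nc <- sample(3:8, 1)
        bubbles[[i]] <- list(frames = fr,
                             cy = runif(nc, 1, res), cx = runif(nc, 1, res),
                             r = runif(nc, 3, 10) * scale_px)
        bubble_frames <- c(bubble_frames, fr)
      }
    }
    n_spec <- rpois(1, config$specular_rate * duration_s)
    spec_frames <- integer(0)
    speculars <- list()
    if (n_spec > 0) {
      for (i in seq_len(n_spec)) {
        f0 <- sample.int(F, 1)
        fr <- f0:min(F, f0 + sample(1:2, 1) - 1)
        ns <- sample(1:3, 1)
        speculars[[i]] <- list(frames = fr, cy = runif(ns, 1, res),
                               cx = runif(ns, 1, res), r = runif(ns, 1, 3) * scale_px)
        spec_frames <- c(spec_frames, fr)
      }
    }

    yy <- matrix(seq_len(res), res, res)
    xx <- t(yy)
    frames <- array(as.raw(0), dim = c(res, res, 3, F))
    for (f in seq_len(F)) {
      f0 <- f - 1L  # 0-based frame index
      closeup <- in_interval(f0, hard_intervals)
      sc <- if (closeup) 0.35 else 1
      o_f <- if (closeup && f > 1) 0.1 else 1  # close-ups barely move
      Sw <- sample_window(S, 1 + (oy[f] - 1) * o_f, 1 + (ox[f] - 1) * o_f, res, sc)
      L <- Sw
      R <- 0.55 + 0.30 * L + (if (closeup) 0.08 else 0)
      G <- 0.35 + 0.22 * L + (if (closeup) 0.04 else 0)
      B <- 0.30 + 0.18 * L

      if (nrow(polyp_scenes) > 0) {
        for (i in seq_len(nrow(polyp_scenes))) {
          if (f0 >= polyp_scenes$start_frame[i] && f0 < polyp_scenes$end_frame[i]) {
            b <- blob[[i]]
            j <- f0 - polyp_scenes$start_frame[i] + 1
            dy <- yy - b$cy[j]; dx <- xx - b$cx[j]
            u <- (cos(b$th) * dx + sin(b$th) * dy) / b$rx
            v <- (-sin(b$th) * dx + cos(b$th) * dy) / b$ry
            d2 <- u^2 + v^2
            m <- exp(-pmax(d2 - 1, 0) * 3)
            hl <- exp(-d2 / 0.06) * 0.15
            R <- R + config$blob_contrast * (0.9 * m) + hl
            G <- G + config$blob_contrast * (0.5 * m) + hl
            B <- B + config$blob_contrast * (0.3 * m) + hl
          }
        }
      }
      for (bb in bubbles) {
        if (f %in% bb$frames) {
          for (k in seq_along(bb$cy)) {
            d2 <- ((yy - bb$cy[k])^2 + (xx - bb$cx[k])^2) / bb$r[k]^2
            ring <- exp(-(abs(sqrt(d2) - 1) * 4)^2) * 0.35 + exp(-d2 * 2) * 0.1
            R <- R + ring; G <- G + ring; B <- B + ring
          }
        }
      }
      for (sp in speculars) {
        if (f %in% sp$frames) {
          for (k in seq_along(sp$cy)) {
            d2 <- ((yy - sp$cy[k])^2 + (xx - sp$cx[k])^2) / sp$r[k]^2
            mask <- d2 <= 1
            R[mask] <- 1; G[mask] <- 1; B[mask] <- 1
          }
        }
      }
      if (f %in% blur_frames) {
        k <- max(2, round(3 * scale_px))
        R <- blur_mat(R, k); G <- blur_mat(G, k); B <- blur_mat(B, k)
      }
      img <- as.integer(round(clamp01(c(R, G, B)) * 255))
      frames[, , , f] <- as.raw(img)
    }

    ann <- frame_annotations(F, polyp_scenes)
    noise_frames <- dplyr::bind_rows(
      tibble::tibble(frame = blur_frames - 1L, type = "blur"),
      tibble::tibble(frame = unique(bubble_frames) - 1L, type = "bubble"),
      tibble::tibble(frame = unique(spec_frames) - 1L, type = "specular"))
    rec <- video_record(video_id, frames, ann, patient_id = patient_id,
                        fps = config$fps,
                        hard_negative = kind == "hard_negative", split = split)
    structure(list(record = rec,
                   provenance = list(polyp_scenes = polyp_scenes,
                                     noise_frames = noise_frames,
                                     hard_intervals = hard_intervals,
                                     kind = kind, video_seed = video_seed)),
              class = "synth_video")
  })
}

# chunk counts by majority label from annotations alone (no frames needed)
count_chunks_by_label <- function(annotations, chunk_len = 16, overlap = 8) {
  F <- nrow(annotations)
  stride <- chunk_len - overlap
  if (F < chunk_len) return(c(polyp = 0L, nonpolyp = 0L))
  starts <- seq(0L, F - chunk_len, by = stride)
  is_p <- annotations$label == "polyp"
  cs <- cumsum(c(0L, is_p))
  npos <- cs[starts + chunk_len + 1] - cs[starts + 1]
  n_polyp <- sum(npos * 2 >= chunk_len)
  c(polyp = n_polyp, nonpolyp = length(starts) - n_polyp)
}

allocate_splits <- function(n, fractions) {
  counts <- floor(n * fractions)
  while (sum(counts) < n) {
    i <- which.max(n * fractions - counts)
    counts[i] <- counts[i] + 1
  }
  if (n >= 3) {
    while (any(counts == 0)) {
      counts[which.max(counts)] <- max(counts) - 1
      counts[which(counts == 0)[1]] <- 1
    }
  }
  rep(names(fractions), counts)
}

#' Generate a patient-disjoint synthetic dataset
#'
#' Draws per-video seeds from the dataset seed, assigns each video a unique
#' patient and a train/validation/test split, flags the configured fraction
#' of non-polyp videos as hard-negative sources, and chooses the per-video
#' polyp-scene coverage so the realized chunk imbalance lands on the target
#' ratio. Errors when the requested ratio is unreachable with the configured
#' durations and scene lengths.
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset`: list with `videos` (list of `synth_video`),
#'   `manifest` (per-video tibble), `realized_imbalance`, `config`.
#' @export
generate_dataset <- function(config) {
  n <- config$n_videos
  if (n < 3) abort("n_videos must be >= 3 (one video per split)")
  pos_frac <- 1 / (1 + config$target_imbalance)
  coverage <- pos_frac / config$polyp_video_fraction
  max_cov <- 0.85
  if (coverage > max_cov) {
    achievable <- (1 - max_cov * config$polyp_video_fraction) /
      (max_cov * config$polyp_video_fraction)
    abort(sprintf(
      "imbalance target 1:%.2f unreachable: needs polyp coverage %.2f > %.2f; achievable ratio >= 1:%.2f with this polyp_video_fraction",
      config$target_imbalance, coverage, max_cov, achievable))
  }

  n_polyp <- max(1L, round(n * config$polyp_video_fraction))
  n_non <- n - n_polyp
  n_hard <- round(config$hard_negative_fraction * n_non)

  with_seed(config$seed, {
    video_seeds <- sample.int(2147483646L, n)
    durations <- runif(n, config$duration_s[1], config$duration_s[2])
    kind <- c(rep("polyp", n_polyp),
              rep("hard_negative", n_hard),
              rep("nonpolyp", n_non - n_hard))
    # splits assigned within kind groups so every split sees each kind when
    # counts allow
    split <- unlist(lapply(split(seq_len(n), kind), function(idx) {
      sample(allocate_splits(length(idx), config$split_fractions))
    }))[order(unlist(split(seq_len(n), kind)))]
    split <- unname(split)
    # every configured split must hold at least one video
    for (s in names(config$split_fractions)) {
      if (config$split_fractions[s] > 0 && !any(split == s)) {
        donor <- names(which.max(table(split)))
        split[which(split == donor)[1]] <- s
      }
    }
  })

  # chunk-level targeting with feedback: each polyp video's scene coverage is
  # set so the cumulative positive-chunk count tracks the dataset target,
  # absorbing per-video placement noise and the boundary-window label bias
  stride <- config$chunk_len - config$overlap
  frames_i <- round(durations * config$fps)
  windows_i <- pmax(0, floor((frames_i - config$chunk_len) / stride) + 1)
  p_target <- sum(windows_i) / (1 + config$target_imbalance)
  mean_len <- mean(config$scene_len_s) * config$fps
  is_polyp_video <- kind == "polyp"
  p_done <- 0

  plan_windows <- function(plan, F) {
    ann <- frame_annotations(F, plan)
    count_chunks_by_label(ann, config$chunk_len, config$overlap)[["polyp"]]
  }

  videos <- vector("list", n)
  for (i in seq_len(n)) {
    plan_i <- NULL
    if (is_polyp_video[i]) {
      w_rem <- sum(windows_i[is_polyp_video & seq_len(n) >= i])
      frac <- (p_target - p_done) / max(w_rem, 1)
      frac <- min(max(frac, 0.02), max_cov)
      F_i <- frames_i[i]
      p_want <- frac * windows_i[i]
      # seeded plan search: draw a scene plan, count the positive windows it
      # yields, and adapt the frame target until the count lands within one
      # window of the video's share
      m_hat <- min(mean_len, frac * F_i)
      target <- round(frac * F_i * m_hat / (m_hat + stride))
      best_err <- Inf
      for (attempt in 1:8) {
        plan <- with_seed(derive_seed(video_seeds[i], 101L + attempt),
                          place_scenes(F_i, config$fps, config$scene_len_s,
                                       target_frames = target))
        err <- plan_windows(plan, F_i) - p_want
        if (abs(err) < abs(best_err)) {
          best_err <- err
          plan_i <- plan
        }
        if (abs(best_err) <= 1) break
        target <- max(0, round(target - err * stride))
      }
      p_done <- p_done + plan_windows(plan_i, F_i)
    }
    videos[[i]] <- generate_video(
      config, video_seeds[i],
      video_id = sprintf("v%03d", i), patient_id = sprintf("p%03d", i),
      kind = kind[i], duration_s = durations[i], polyp_scenes = plan_i,
      split = split[i])
  }

  manifest <- purrr::map_dfr(videos, function(v) {
    cnt <- count_chunks_by_label(v$record$annotations, config$chunk_len,
                                 config$overlap)
    tibble::tibble(video_id = v$record$video_id,
                   patient_id = v$record$patient_id,
                   split = v$record$split, kind = v$provenance$kind,
                   hard_negative = v$record$hard_negative,
                   frames = v$record$frame_count,
                   polyp_frames = sum(v$record$annotations$label == "polyp"),
                   polyp_chunks = cnt["polyp"], nonpolyp_chunks = cnt["nonpolyp"])
  })
  realized <- sum(manifest$nonpolyp_chunks) / max(1, sum(manifest$polyp_chunks))
  if (abs(realized - config$target_imbalance) / config$target_imbalance > 0.10) {
    abort(sprintf(
      "realized chunk imbalance 1:%.2f misses target 1:%.2f by more than 10%%; adjust durations or scene lengths",
      realized, config$target_imbalance))
  }
  structure(list(videos = videos, manifest = manifest,
                 realized_imbalance = realized, config = config),
            class = "synth_dataset")
}

#' Chunk a synthetic dataset by split
#'
#' @param dataset A [generate_dataset()] result.
#' @param overlap Chunk overlap in frames.
#' @return List with one `chunk_set` per split plus `hard_video_ids`.
#' @export
extract_dataset_chunks <- function(dataset, overlap = NULL) {
  overlap <- overlap %||% dataset$config$overlap
  sets <- lapply(dataset$videos, function(v) {
    extract_chunks(v$record, chunk_len = dataset$config$chunk_len,
                   overlap = overlap, size = dataset$config$frame_size)
  })
  splits <- vapply(dataset$videos, function(v) v$record$split, character(1))
  out <- lapply(unique(splits), function(s) bind_chunk_sets(sets[splits == s]))
  names(out) <- unique(splits)
  out$hard_video_ids <- dataset$manifest$video_id[dataset$manifest$hard_negative]
  out
}
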