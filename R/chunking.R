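#' Construct a video record
#'
#' A video record bundles a frame source with its per-frame annotations and
#' dataset metadata. Frames can be held in memory as a `H x W x 3 x F` uint8
#' raw array (what the synthetic generator produces) or referenced as a
#' directory of zero-padded PNG images that is read lazily during chunk
#' extraction.
#'
#' @param video_id,patient_id Identifiers. Splits must never share a
#'   `patient_id`.
#' @param frames Either a raw array with dim `c(H, W, 3, F)` (values 0..255)
#'   or a character path to a directory of PNG frames in frame order.
#' @param annotations A tibble with columns `frame_index` (0-based),
#'   `label` (`"polyp"`/`"nonpolyp"`) and `modality` (`"white_light"`,
#'   `"nbi"`, `"staining"`), one row per frame covering `[0, frame_count)`.
#' @param fps Frames per second (default 30).
#' @param hard_negative Whether this video was flagged as a hard-negative
#'   source (near-wall close-ups, bubbles, specula).
#' @param split One of `"train"`, `"validation"`, `"test"`, or `NA`.
#' @return An object of class `video_record`.
#' @export
video_record <- function(video_id, frames, annotations, patient_id = video_id,
                         fps = 30, hard_negative = FALSE, split = NA_character_) {
  frame_count <- n_source_frames(frames)
  annotations <- validate_annotations(annotations, frame_count)
  structure(
    list(video_id = as.character(video_id), patient_id = as.character(patient_id),
         fps = fps, frame_count = frame_count, frames = frames,
         annotations = annotations, hard_negative = isTRUE(hard_negative),
         split = split),
    class = "video_record")
}

n_source_frames <- function(frames) {
  if (is.character(frames)) {
    length(list_frame_files(frames))
  } else if (is.array(frames) && length(dim(frames)) == 4) {
    dim(frames)[4]
  } else {
    abort("`frames` must be an H x W x 3 x F array or a frame directory path")
  }
}

list_frame_files <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no PNG frames found in '%s'", dir))
  files
}

validate_annotations <- function(annotations, frame_count) {
  annotations <- tibble::as_tibble(annotations)
  need <- c("frame_index", "label")
  if (!all(need %in% names(annotations))) {
    abort("annotations need columns frame_index and label")
  }
  if (!("modality" %in% names(annotations))) annotations$modality <- "white_light"
  annotations <- dplyr::arrange(annotations, .data$frame_index)
  if (!identical(as.integer(annotations$frame_index), seq_len(frame_count) - 1L)) {
    abort(sprintf(
      "annotations must cover every frame in [0, %d) exactly once", frame_count))
  }
  check_labels(annotations$label)
  bad <- setdiff(unique(annotations$modality), MODALITIES)
  if (length(bad) > 0) abort(sprintf("invalid modality: %s", paste(bad, collapse = ", ")))
  annotations
}

#' Per-frame annotations from scene intervals
#'
#' Expands half-open scene intervals into the one-row-per-frame annotation
#' table used by [video_record()]. Frames not covered by any polyp interval
#' are labelled `nonpolyp`; frames not covered by a modality interval get
#' `white_light`.
#'
#' @param frame_count Total number of frames.
#' @param polyp_scenes Tibble with `start_frame`, `end_frame` (half-open) of
#'   polyp intervals; may be empty.
#' @param modality_intervals Optional tibble with `start_frame`, `end_frame`,
#'   `modality`.
#' @return Tibble with `frame_index`, `label`, `modality`.
#' @export
frame_annotations <- function(frame_count, polyp_scenes = NULL,
                              modality_intervals = NULL) {
  label <- rep("nonpolyp", frame_count)
  if (!is.null(polyp_scenes) && nrow(polyp_scenes) > 0) {
    for (i in seq_len(nrow(polyp_scenes))) {
      a <- polyp_scenes$start_frame[i]
      b <- polyp_scenes$end_frame[i]
      if (a < 0 || b > frame_count || a >= b) {
        abort(sprintf("polyp scene [%d, %d) outside video of %d frames", a, b, frame_count))
      }
      label[(a + 1):b] <- "polyp"
    }
  }
  modality <- rep("white_light", frame_count)
  if (!is.null(modality_intervals) && nrow(modality_intervals) > 0) {
    for (i in seq_len(nrow(modality_intervals))) {
      a <- modality_intervals$start_frame[i]
      b <- modality_intervals$end_frame[i]
      modality[(a + 1):b] <- modality_intervals$modality[i]
    }
  }
  tibble::tibble(frame_index = seq_len(frame_count) - 1L, label = label,
                 modality = modality)
}

#' Maximal constant-label runs as scene intervals
#'
#' Collapses a complete per-frame label sequence into half-open
#' `[start_frame, end_frame)` intervals of constant label. Concatenating the
#' intervals reproduces the input exactly (round-trip identity).
#'
#' @param annotations Tibble with `frame_index` (complete, 0-based) and
#'   `label`, as in [video_record()].
#' @return Tibble with `start_frame`, `end_frame`, `label`, sorted and
#'   disjoint.
#' @export
scenes_from_annotations <- function(annotations) {
  annotations <- dplyr::arrange(tibble::as_tibble(annotations), .data$frame_index)
  fi <- as.integer(annotations$frame_index)
  if (length(fi) == 0 || !identical(fi, seq_along(fi) - 1L)) {
    abort("annotations must cover frames 0..F-1 without gaps")
  }
  r <- rle(as.character(annotations$label))
  ends <- cumsum(r$lengths)
  tibble::tibble(
    start_frame = c(0L, head(ends, -1)),
    end_frame = as.integer(ends),
    label = r$values)
}

#' Majority label of a chunk window
#'
#' A 16-frame chunk inherits the majority label of its frames; ties go to
#' `polyp` so that boundary windows at scene edges favour sensitivity.
#'
#' @param annotations Per-frame annotation tibble covering the window.
#' @param start_frame 0-based first frame of the window.
#' @param chunk_len Window length in frames.
#' @return `"polyp"` or `"nonpolyp"`.
#' @export
label_chunk <- function(annotations, start_frame, chunk_len = 16) {
  idx <- start_frame:(start_frame + chunk_len - 1)
  lab <- annotations$label[match(idx, annotations$frame_index)]
  if (anyNA(lab)) {
    abort(sprintf("missing frame annotation in window [%d, %d)",
                  start_frame, start_frame + chunk_len))
  }
  n_polyp <- sum(lab == "polyp")
  if (n_polyp * 2 >= chunk_len) "polyp" else "nonpolyp"
}

#' Extract overlapping chunks from a video
#'
#' Slides a `chunk_len`-frame window over the video with stride
#' `chunk_len - overlap`, anchored at frame 0. Windows containing any
#' non-white-light frame are skipped. Frames are bilinearly resized to
#' 112 x 112 (full frame, no cropping) when needed and stored as uint8 in
#' `[0, 255]`; [chunk_tensor()] rescales to `[0, 1]` doubles.
#'
#' @param video A [video_record()].
#' @param chunk_len Frames per chunk (default 16).
#' @param overlap Frames shared by successive chunks; `0 <= overlap <
#'   chunk_len`. The chunk-level convention is 8; the scene-level evaluation
#'   convention is 4.
#' @param size Spatial side length of the stored tensor (default 112).
#' @return A `chunk_set`: a tibble with columns `chunk_id`, `video_id`,
#'   `start_frame`, `label` and a list-column `tensor` of raw vectors, with
#'   attributes `chunk_len`, `stride`, `size`, `fps`.
#' @export
extract_chunks <- function(video, chunk_len = 16, overlap = 8, size = 112) {
  stopifnot(inherits(video, "video_record"))
  if (overlap < 0 || overlap >= chunk_len) {
    abort(sprintf("overlap must satisfy 0 <= overlap < chunk_len, got %d", overlap))
  }
  stride <- chunk_len - overlap
  F <- video$frame_count
  starts <- integer(0)
  if (F >= chunk_len) starts <- seq(0L, F - chunk_len, by = stride)

  wl <- video$annotations$modality == "white_light"
  keep <- vapply(starts, function(s) all(wl[(s + 1):(s + chunk_len)]), logical(1))
  starts <- starts[keep]

  tensors <- vector("list", length(starts))
  labels <- character(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    fr <- read_frames(video, s + seq_len(chunk_len) - 1L, size = size)
    # fr: size x size x 3 x chunk_len uint8 -> chunk layout (T, H, W, C)
    tensors[[i]] <- as.raw(aperm(fr, c(4, 1, 2, 3)))
    labels[i] <- label_chunk(video$annotations, s, chunk_len)
  }
  out <- tibble::tibble(
    chunk_id = sprintf("%s#%06d", video$video_id, starts),
    video_id = video$video_id,
    start_frame = as.integer(starts),
    label = labels,
    tensor = tensors)
  new_chunk_set(out, chunk_len = chunk_len, stride = stride, size = size,
                fps = video$fps)
}

new_chunk_set <- function(df, chunk_len, stride, size, fps) {
  structure(df, chunk_len = chunk_len, stride = stride, size = size, fps = fps,
            class = c("chunk_set", class(tibble::tibble())))
}

#' Combine chunk sets from several videos
#'
#' @param chunk_sets A list of `chunk_set` objects sharing one stride.
#' @return A single `chunk_set`.
#' @export
bind_chunk_sets <- function(chunk_sets) {
  chunk_sets <- chunk_sets[vapply(chunk_sets, nrow, integer(1)) > 0]
  if (length(chunk_sets) == 0) abort("no non-empty chunk sets to bind")
  strides <- unique(vapply(chunk_sets, function(x) attr(x, "stride"), numeric(1)))
  if (length(strides) != 1) abort("chunk sets have differing strides")
  out <- dplyr::bind_rows(lapply(chunk_sets, tibble::as_tibble))
  a <- chunk_sets[[1]]
  new_chunk_set(out, attr(a, "chunk_len"), attr(a, "stride"), attr(a, "size"),
                attr(a, "fps"))
}

#' Subset a chunk set, preserving its metadata
#'
#' @param chunks A `chunk_set`.
#' @param idx Row indices (or a logical mask).
#' @return A `chunk_set` with the selected rows.
#' @export
chunk_subset <- function(chunks, idx) {
  new_chunk_set(tibble::as_tibble(chunks)[idx, ], attr(chunks, "chunk_len"),
                attr(chunks, "stride"), attr(chunks, "size"), attr(chunks, "fps"))
}

#' Materialise one chunk tensor
#'
#' @param chunks A `chunk_set`.
#' @param i Row index.
#' @return A `chunk_len x size x size x 3` double array with values in
#'   `[0, 1]`.
#' @export
chunk_tensor <- function(chunks, i) {
  chunk_len <- attr(chunks, "chunk_len") %||% 16
  size <- attr(chunks, "size") %||% 112
  x <- as.integer(chunks$tensor[[i]]) / 255
  array(x, dim = c(chunk_len, size, size, 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read frames `idx` (0-based) from a record as a size x size x 3 x n uint8
# integer array, resizing bilinearly when the source resolution differs.
read_frames <- function(video, idx, size = 112) {
  n <- length(idx)
  if (is.character(video$frames)) {
    files <- list_frame_files(video$frames)
    out <- array(0L, dim = c(size, size, 3, n))
    for (j in seq_len(n)) {
      f <- files[idx[j] + 1]
      if (is.na(f) || !file.exists(f)) {
        abort(sprintf("unreadable frame %d of video '%s'", idx[j], video$video_id))
      }
      img <- png::readPNG(f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
      img <- img[, , 1:3, drop = FALSE]
      out[, , , j] <- resize_frame_u8(img, size)
    }
    out
  } else {
    fr <- video$frames[, , , idx + 1, drop = FALSE]
    fr <- array(as.integer(fr), dim = dim(fr))
    if (dim(fr)[1] != size || dim(fr)[2] != size) {
      res <- array(0L, dim = c(size, size, 3, n))
      for (j in seq_len(n)) res[, , , j] <- resize_frame_u8(fr[, , , j] / 255, size)
      fr <- res
    }
    fr
  }
}

# Bilinear full-frame resize of an H x W x 3 double image in [0,1] to
# size x size, returned as integer 0..255.
resize_frame_u8 <- function(img, size) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    r <- EBImage::resize(img, w = size, h = size)
    r <- pmin(pmax(r, 0), 1)
    array(as.integer(round(r * 255)), dim = c(size, size, 3))
  } else {
    h <- dim(img)[1]; w <- dim(img)[2]
    ys <- (seq_len(size) - 0.5) * h / size + 0.5
    xs <- (seq_len(size) - 0.5) * w / size + 0.5
    y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h); fy <- ys - y0
    x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w); fx <- xs - x0
    out <- array(0, dim = c(size, size, 3))
    for (c in 1:3) {
      ch <- img[, , c]
      a <- ch[y0, x0]; b <- ch[y0, x1]; d <- ch[y1, x0]; e <- ch[y1, x1]
      top <- a * (1 - rep(fx, each = size)) + b * rep(fx, each = size)
      bot <- d * (1 - rep(fx, each = size)) + e * rep(fx, each = size)
      out[, , c] <- top * (1 - fy) + bot * fy
    }
    array(as.integer(round(pmin(pmax(out, 0), 1) * 255)), dim = c(size, size, 3))
  }
}

#' Read or write annotation files
#'
#' The JSON layout is
#' `{video_id, fps, hard_negative, scenes: [{start, end, label}], modality_intervals: [...]}`
#' with half-open 0-based frame intervals; the CSV alternative is one row per
#' frame with columns `frame_index,label,modality`.
#'
#' @param path File path (`.json` or `.csv`).
#' @param frame_count Total frames (needed to expand JSON scene lists).
#' @return For readers, a list with `annotations` (per-frame tibble), `fps`,
#'   `hard_negative`, `video_id`.
#' @export
read_annotations <- function(path, frame_count = NULL) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(frame_count)) frame_count <- j$frame_count
    if (is.null(frame_count)) abort("frame_count needed to expand JSON scenes")
    sc <- tibble::as_tibble(j$scenes)
    polyp <- sc[sc$label == "polyp", , drop = FALSE]
    polyp_scenes <- tibble::tibble(start_frame = as.integer(polyp$start),
                                   end_frame = as.integer(polyp$end))
    mi <- NULL
    if (!is.null(j$modality_intervals) && length(j$modality_intervals) > 0) {
      m <- tibble::as_tibble(j$modality_intervals)
      mi <- tibble::tibble(start_frame = as.integer(m$start),
                           end_frame = as.integer(m$end), modality = m$modality)
    }
    list(annotations = frame_annotations(frame_count, polyp_scenes, mi),
         fps = j$fps %||% 30, hard_negative = isTRUE(j$hard_negative),
         video_id = j$video_id)
  } else {
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    list(annotations = df[, c("frame_index", "label", "modality")],
         fps = 30, hard_negative = FALSE, video_id = NULL)
  }
}

#' @rdname read_annotations
#' @param video A [video_record()] to serialise.
#' @export
write_annotations <- function(video, path) {
  scenes <- scenes_from_annotations(video$annotations)
  j <- list(video_id = video$video_id, fps = video$fps,
            frame_count = video$frame_count,
            hard_negative = video$hard_negative,
            scenes = data.frame(start = scenes$start_frame, end = scenes$end_frame,
                                label = scenes$label))
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write video frames as a PNG directory
#'
#' @param video A [video_record()] with in-memory frames.
#' @param dir Output directory (created if missing).
#' @export
write_video_frames <- function(video, dir) {
  if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(video$frame_count)) {
    img <- array(as.integer(video$frames[, , , f]) / 255,
                 dim = dim(video$frames)[1:3])
    png::writePNG(img, file.path(dir, sprintf("frame_%06d.png", f - 1)))
  }
  invisible(dir)
}

#' Cache a chunk set on disk
#'
#' Tensors are kept in their uint8 raw form. The cache uses R native
#' serialization.
#'
#' @param chunks A `chunk_set`.
#' @param path Cache file path.
#' @export
write_chunk_cache <- function(chunks, path) {
  saveRDS(list(meta = tibble::as_tibble(chunks)[, c("chunk_id", "video_id",
                                                    "start_frame", "label")],
               tensors = chunks$tensor,
               chunk_len = attr(chunks, "chunk_len"), stride = attr(chunks, "stride"),
               size = attr(chunks, "size"), fps = attr(chunks, "fps")),
          path)
  invisible(path)
}

#' @rdname write_chunk_cache
#' @export
read_chunk_cache <- function(path) {
  x <- readRDS(path)
  df <- x$meta
  df$tensor <- x$tensors
  new_chunk_set(df, x$chunk_len, x$stride, x$size, x$fps)
}
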