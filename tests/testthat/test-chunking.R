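# Sliding-window chunk extraction, labeling and scene intervals.

make_video <- function(F, labels = rep("nonpolyp", F), size = 20,
                       modality = "white_light", seed = 1) {
  frames <- polypscene:::with_seed(seed, {
    array(as.raw(sample(0:255, size * size * 3 * F, replace = TRUE)),
          dim = c(size, size, 3, F))
  })
  video_record("vid", frames, ann_from_labels(labels, modality), fps = 30)
}

test_that("chunk count follows floor((F - chunk_len)/stride) + 1", {
  ch <- extract_chunks(make_video(32), chunk_len = 16, overlap = 8, size = 20)
  expect_equal(ch$start_frame, c(0L, 8L, 16L))
  expect_equal(nrow(extract_chunks(make_video(16), overlap = 8, size = 20)), 1)
  expect_equal(nrow(extract_chunks(make_video(15), overlap = 8, size = 20)), 0)
  expect_equal(nrow(extract_chunks(make_video(60), overlap = 4, size = 20)), 4)
})

test_that("chunk enumeration matches a brute-force window scan", {
  brute <- function(F, chunk_len, stride) {
    starts <- integer(0)
    s <- 0
    while (s + chunk_len <= F) {
      starts <- c(starts, s)
      s <- s + stride
    }
    starts
  }
  polypscene:::with_seed(99, {
    for (rep in 1:25) {
      F <- sample(10:90, 1)
      overlap <- sample(0:15, 1)
      ch <- extract_chunks(make_video(F), chunk_len = 16, overlap = overlap,
                           size = 20)
      expect_equal(ch$start_frame, brute(F, 16, 16 - overlap))
      if (nrow(ch) > 1) {
        expect_true(all(diff(ch$start_frame) == 16 - overlap))
      }
    }
  })
})

test_that("extracted tensors have the declared shape and unit range", {
  ch <- extract_chunks(make_video(40, size = 112), overlap = 8)
  x <- chunk_tensor(ch, 1)
  expect_equal(dim(x), c(16, 112, 112, 3))
  expect_true(all(x >= 0 & x <= 1))
  # values survive the round trip from the source frames
  v <- make_video(40, size = 112)
  expect_equal(as.vector(x[1, , , ]),
               as.integer(v$frames[, , , 1]) / 255, tolerance = 1e-12)
})

test_that("frames are resized bilinearly when the source is larger", {
  v <- make_video(20, size = 56)
  ch <- extract_chunks(v, overlap = 8, size = 112)
  expect_equal(dim(chunk_tensor(ch, 1)), c(16, 112, 112, 3))
})

test_that("invalid overlap and unreadable frames raise clear errors", {
  expect_error(extract_chunks(make_video(32), overlap = 16, size = 20), "overlap")
  v <- make_video(32)
  v$frames <- file.path(tempfile(), "nope")
  expect_error(extract_chunks(v, overlap = 8, size = 20), "PNG|frame")
})

test_that("a PNG frame directory round-trips through extraction", {
  skip_if_not_installed("png")
  v <- make_video(20, size = 32, seed = 5)
  dir <- file.path(tempdir(), "frames_rt")
  write_video_frames(v, dir)
  v2 <- video_record("vid", dir, v$annotations, fps = 30)
  expect_equal(v2$frame_count, 20)
  c1 <- extract_chunks(v, overlap = 8, size = 32)
  c2 <- extract_chunks(v2, overlap = 8, size = 32)
  expect_identical(c1$tensor, c2$tensor)
  unlink(dir, recursive = TRUE)
})

test_that("chunk labels follow frame majority with ties going to polyp", {
  ann <- ann_from_labels(rep(c("polyp", "nonpolyp"), c(16, 16)))
  expect_equal(label_chunk(ann, 0), "polyp")     # unanimous polyp
  expect_equal(label_chunk(ann, 16), "nonpolyp") # unanimous nonpolyp
  ann9 <- ann_from_labels(rep(c("polyp", "nonpolyp"), c(9, 7)))
  expect_equal(label_chunk(ann9, 0), "polyp")    # 9 of 16
  ann8 <- ann_from_labels(rep(c("polyp", "nonpolyp"), c(8, 8)))
  expect_equal(label_chunk(ann8, 0), "polyp")    # tie
  ann7 <- ann_from_labels(rep(c("polyp", "nonpolyp"), c(7, 9)))
  expect_equal(label_chunk(ann7, 0), "nonpolyp")
  expect_error(label_chunk(ann8, 5), "missing")
})

test_that("non-white-light windows are excluded from chunking", {
  labels <- rep("nonpolyp", 48)
  modality <- rep("white_light", 48)
  modality[20:30] <- "nbi"
  v <- make_video(48, labels)
  v$annotations$modality <- modality
  ch <- extract_chunks(v, overlap = 8, size = 20)
  # windows starting at 8, 16, 24 touch the nbi frames 19..29 (0-based)
  expect_equal(ch$start_frame, c(0L, 32L))
})

test_that("scenes_from_annotations produces maximal runs and round-trips", {
  ann <- ann_from_labels(c("nonpolyp", "nonpolyp", "polyp", "polyp", "polyp",
                           "nonpolyp"))
  sc <- scenes_from_annotations(ann)
  expect_equal(sc$start_frame, c(0L, 2L, 5L))
  expect_equal(sc$end_frame, c(2L, 5L, 6L))
  expect_equal(sc$label, c("nonpolyp", "polyp", "nonpolyp"))

  expect_equal(nrow(scenes_from_annotations(ann_from_labels(rep("nonpolyp", 9)))), 1)
  alt <- ann_from_labels(rep(c("polyp", "nonpolyp"), 5))
  expect_equal(nrow(scenes_from_annotations(alt)), 10)

  # round trip: expanding the intervals reproduces the labels, for random input
  polypscene:::with_seed(3, {
    for (rep in 1:20) {
      labs <- sample(c("polyp", "nonpolyp"), sample(1:60, 1), replace = TRUE)
      sc <- scenes_from_annotations(ann_from_labels(labs))
      back <- unlist(mapply(function(s, e, l) rep(l, e - s),
                            sc$start_frame, sc$end_frame, sc$label))
      expect_equal(unname(back), labs)
      expect_true(all(sc$start_frame < sc$end_frame))
      expect_equal(sc$start_frame[-1], sc$end_frame[-nrow(sc)])
    }
  })
  expect_error(scenes_from_annotations(ann_from_labels(c("polyp"))[0, ]), "cover")
})

test_that("annotation JSON round-trips through read/write", {
  v <- make_video(30, c(rep("nonpolyp", 10), rep("polyp", 12), rep("nonpolyp", 8)))
  path <- tempfile(fileext = ".json")
  write_annotations(v, path)
  back <- read_annotations(path)
  expect_equal(back$annotations$label, v$annotations$label)
  expect_equal(back$fps, 30)
  unlink(path)
})

test_that("the chunk cache preserves tensors and metadata", {
  ch <- extract_chunks(make_video(40), overlap = 8, size = 20)
  path <- tempfile(fileext = ".rds")
  write_chunk_cache(ch, path)
  back <- read_chunk_cache(path)
  expect_identical(back$tensor, ch$tensor)
  expect_equal(back$label, ch$label)
  expect_equal(attr(back, "stride"), attr(ch, "stride"))
  unlink(path)
})
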