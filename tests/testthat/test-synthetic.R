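# The seeded synthetic video generator and dataset assembly.

test_that("explicit scene plans produce exact polyp frame counts", {
  cfg <- synth_config(seed = 1)
  scenes <- tibble::tibble(start_frame = c(30L, 200L), end_frame = c(120L, 290L))
  v <- generate_video(cfg, 5, kind = "polyp", duration_s = 12,
                      polyp_scenes = scenes)
  # 2 scenes of 3 s at 30 fps
  expect_equal(sum(v$record$annotations$label == "polyp"), 180)
  got <- scenes_from_annotations(v$record$annotations)
  expect_equal(got$start_frame[got$label == "polyp"], scenes$start_frame)
  expect_equal(got$end_frame[got$label == "polyp"], scenes$end_frame)
})

test_that("same seed gives byte-identical frames; zero rates give no noise", {
  cfg <- synth_config(blur_rate = 0, bubble_rate = 0, specular_rate = 0)
  v1 <- generate_video(cfg, 77, kind = "polyp", duration_s = 3)
  v2 <- generate_video(cfg, 77, kind = "polyp", duration_s = 3)
  expect_identical(v1$record$frames, v2$record$frames)
  expect_equal(nrow(v1$provenance$noise_frames), 0)
  v3 <- generate_video(cfg, 78, kind = "polyp", duration_s = 3)
  expect_false(identical(v1$record$frames, v3$record$frames))
})

test_that("provenance round-trips through the annotation pipeline", {
  ds <- small_dataset()
  for (v in ds$videos) {
    sc <- scenes_from_annotations(v$record$annotations)
    polyp <- sc[sc$label == "polyp", c("start_frame", "end_frame")]
    expect_equal(as.data.frame(polyp),
                 as.data.frame(v$provenance$polyp_scenes[, c("start_frame", "end_frame")]))
  }
})

test_that("dataset assembly flags hard negatives and separates patients", {
  ds <- small_dataset()
  m <- ds$manifest
  expect_equal(nrow(m), 6)
  expect_false(any(duplicated(m$patient_id)))
  n_non <- sum(m$kind != "polyp")
  expect_equal(sum(m$hard_negative), round(0.2 * n_non))
  expect_true(all(m$hard_negative == (m$kind == "hard_negative")))
  # every split occupied
  expect_setequal(unique(m$split), c("train", "validation", "test"))
  # realized imbalance within 10% of the target
  expect_lt(abs(ds$realized_imbalance - 3.16) / 3.16, 0.10)
})

test_that("a minimal three-video dataset puts one video per split", {
  cfg <- synth_config(n_videos = 3, duration_s = c(8, 10), polyp_video_fraction = 1 / 3,
                      target_imbalance = 3.2, seed = 21)
  ds <- generate_dataset(cfg)
  expect_equal(sort(ds$manifest$split), sort(c("train", "validation", "test")))
})

test_that("a 1:1 target with equal durations is realized within 10%", {
  cfg <- synth_config(n_videos = 6, duration_s = c(11, 11),
                      polyp_video_fraction = 2 / 3, target_imbalance = 1,
                      seed = 31)
  ds <- generate_dataset(cfg)
  expect_gte(ds$realized_imbalance, 0.9)
  expect_lte(ds$realized_imbalance, 1.1)
})

test_that("unreachable imbalance targets raise a config error", {
  cfg <- synth_config(n_videos = 6, duration_s = c(10, 11),
                      polyp_video_fraction = 0.25, target_imbalance = 1,
                      seed = 41)
  expect_error(generate_dataset(cfg), "achievable")
})

test_that("dataset-level seed fully determines the output", {
  cfg <- synth_config(n_videos = 3, duration_s = c(8, 9), seed = 13)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$videos[[1]]$record$frames, d2$videos[[1]]$record$frames)
})

test_that("a luminance-contrast detector separates the classes (AUC > 0.9)", {
  ds <- small_dataset()
  ch <- extract_dataset_chunks(ds)
  all_chunks <- bind_chunk_sets(list(ch$train, ch$validation, ch$test))
  score <- vapply(seq_len(nrow(all_chunks)), function(i) {
    x <- chunk_tensor(all_chunks, i)[, , , 1]
    k <- max(1L, round(0.02 * length(x)))
    mean(sort(x, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
  is_pos <- all_chunks$label == "polyp"
  expect_gt(sum(is_pos), 10)
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  auc <- (sum(rank(score)[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  expect_gt(auc, 0.9)
})

test_that("large-frame rendering exercises the resize path", {
  cfg <- synth_config(render_size = 448, blur_rate = 0, bubble_rate = 0,
                      specular_rate = 0)
  v <- generate_video(cfg, 3, kind = "polyp", duration_s = 0.6,
                      polyp_scenes = tibble::tibble(start_frame = 0L,
                                                    end_frame = 18L))
  expect_equal(dim(v$record$frames)[1:2], c(448, 448))
  ch <- extract_chunks(v$record, overlap = 8, size = 112)
  expect_equal(dim(chunk_tensor(ch, 1)), c(16, 112, 112, 3))
})
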