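# Chunk-level threshold sweeps and scene-level detection/FP reporting.

test_that("chunk metrics hit hand-computed values", {
  sep <- tibble::tibble(prob_polyp = c(0.9, 0.9, 0.1, 0.1),
                        label = c("polyp", "polyp", "nonpolyp", "nonpolyp"))
  r <- chunk_metrics(sep, tau_grid = 0.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  zeros <- tibble::tibble(prob_polyp = rep(0, 6),
                          label = rep(c("polyp", "nonpolyp"), 3))
  rz <- chunk_metrics(zeros)
  expect_true(all(rz$sensitivity == 0))
  expect_true(all(rz$specificity == 1))
  expect_equal(nrow(rz), 19)  # default grid 0.05..0.95

  mixed <- tibble::tibble(prob_polyp = c(0.9, 0.6, 0.4, 0.2),
                          label = c("polyp", "nonpolyp", "polyp", "nonpolyp"))
  rm <- chunk_metrics(mixed, tau_grid = 0.5)
  expect_equal(rm$sensitivity, 0.5)
  expect_equal(rm$specificity, 0.5)

  expect_error(chunk_metrics(tibble::tibble(prob_polyp = 0.4, label = "polyp")),
               "nonpolyp")
})

test_that("ROC endpoints and monotonicity hold on random score sets", {
  polypscene:::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(20:80, 1)
      df <- tibble::tibble(prob_polyp = runif(n, 0.01, 0.99),
                           label = sample(c("polyp", "nonpolyp"), n, TRUE))
      if (length(unique(df$label)) < 2) next
      r <- chunk_metrics(df)
      expect_true(all(diff(r$sensitivity) <= 1e-12))
      expect_true(all(diff(1 - r$specificity) <= 1e-12))
      r0 <- chunk_metrics(df, tau_grid = 0.005)
      expect_equal(r0$sensitivity, 1)
      r1 <- chunk_metrics(df, tau_grid = 0.995)
      expect_equal(r1$sensitivity, 0)
      expect_equal(r1$specificity, 1)
    }
  })
})

test_that("post-processing can only raise specificity and lower sensitivity", {
  polypscene:::with_seed(31, {
    for (rep in 1:15) {
      n <- 60
      label <- sample(c("polyp", "nonpolyp"), n, TRUE)
      prob <- runif(n)
      tau <- sample(seq(0.1, 0.9, 0.1), 1)
      flags <- threshold_flags(prob, tau)
      kept <- successive_filter(flags, sample(2:3, 1))
      is_pos <- label == "polyp"
      if (!any(is_pos) || all(is_pos)) next
      expect_lte(mean(kept[is_pos]), mean(flags[is_pos]))       # sensitivity
      expect_gte(mean(1 - kept[!is_pos]), mean(1 - flags[!is_pos]))  # specificity
    }
  })
})

test_that("clip evaluation detects overlap and measures FP durations", {
  gt <- tibble::tibble(start_frame = 100L, end_frame = 250L, label = "polyp")
  # one positive run inside the ground truth
  labs <- rep(0L, 20); labs[10:12] <- 1L  # chunks 9..11 -> frames 108..148
  r <- evaluate_clip(labs, gt, stride = 12, chunk_len = 16, fps = 30)
  expect_true(r$detected)
  expect_equal(r$fp_duration_s, 0)

  r0 <- evaluate_clip(rep(0L, 20), gt, stride = 12)
  expect_false(r0$detected)
  expect_equal(r0$fp_duration_s, 0)

  # a 3-chunk false-positive run far from the ground truth
  labs2 <- rep(0L, 40); labs2[30:32] <- 1L
  gt2 <- tibble::tibble(start_frame = 0L, end_frame = 100L, label = "polyp")
  r2 <- evaluate_clip(labs2, gt2, stride = 12, chunk_len = 16, fps = 30)
  expect_false(r2$detected)
  expect_equal(r2$n_fp_scenes, 1)
  expect_equal(r2$fp_duration_s, 40 / 30, tolerance = 1e-9)

  # sharing a single frame counts as overlap (half-open intervals)
  gt3 <- tibble::tibble(start_frame = 0L, end_frame = 1L, label = "polyp")
  labs3 <- c(1L, 1L)
  r3 <- evaluate_clip(labs3, gt3, stride = 12)
  expect_true(r3$detected)
})

test_that("scene reports aggregate detection accuracy and mean FP duration", {
  clips <- tibble::tibble(
    clip_id = sprintf("c%02d", 1:21),
    detected = rep(c(TRUE, FALSE), c(18, 3)),
    n_fp_scenes = 0L, fp_duration_s = 0, clip_duration_s = 60)
  rep1 <- scene_report(clips)
  expect_equal(rep1$summary$detection_accuracy, 18 / 21, tolerance = 1e-9)
  expect_equal(round(rep1$summary$detection_accuracy, 2), 0.86)

  clips$detected <- TRUE
  expect_equal(scene_report(clips)$summary$detection_accuracy, 1)

  fp <- tibble::tibble(clip_id = c("a", "b", "c"), detected = TRUE,
                       n_fp_scenes = c(2L, 1L, 1L), fp_duration_s = c(6, 6, 6),
                       clip_duration_s = 60)
  rfp <- scene_report(fp)
  expect_equal(rfp$summary$mean_fp_duration_s, 6)
  expect_equal(rfp$summary$mean_fp_duration_s / 60, 0.10)
  expect_equal(rfp$summary$mean_fp_event_duration_s, 18 / 4)
  expect_s3_class(glance(rfp), "tbl_df")
  expect_equal(nrow(tidy(rfp)), 3)
})

test_that("scene report equals a brute-force recount on random cases", {
  polypscene:::with_seed(77, {
    for (rep in 1:10) {
      n_clips <- sample(3:8, 1)
      clips <- purrr::map_dfr(seq_len(n_clips), function(i) {
        L <- sample(10:40, 1)
        labs <- successive_filter(sample(0:1, L, TRUE), 2)
        gt <- tibble::tibble(start_frame = 50L, end_frame = 150L,
                             label = "polyp")
        evaluate_clip(labs, gt, stride = 12, clip_id = sprintf("c%d", i))
      })
      r <- scene_report(clips)
      expect_equal(r$summary$detection_accuracy, sum(clips$detected) / n_clips)
      expect_equal(r$summary$mean_fp_duration_s, sum(clips$fp_duration_s) / n_clips)
    }
  })
})
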