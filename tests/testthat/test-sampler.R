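# Hard/residual negative partitioning, epoch-wise 1:1 subsampling and the
# balanced class weights.

make_pool_chunks <- function(n_videos_pos = 2, n_videos_neg = 4, per_video = 10) {
  vids <- c(sprintf("pos%02d", seq_len(n_videos_pos)),
            sprintf("neg%02d", seq_len(n_videos_neg)))
  labels <- rep(c("polyp", "nonpolyp"), c(n_videos_pos, n_videos_neg) * per_video)
  tibble::tibble(
    chunk_id = sprintf("c%04d", seq_along(labels)),
    video_id = rep(vids, each = per_video),
    label = labels)
}

test_that("negatives are partitioned by hard-video membership", {
  ch <- make_pool_chunks()
  p0 <- partition_negatives(ch, character(0))
  expect_length(p0$hard_ids, 0)
  expect_length(p0$residual_ids, 40)

  pall <- partition_negatives(ch, sprintf("neg%02d", 1:4))
  expect_length(pall$residual_ids, 0)
  expect_length(pall$hard_ids, 40)

  p2 <- partition_negatives(ch, c("neg01", "neg02"))
  expect_length(p2$hard_ids, 20)
  expect_length(p2$residual_ids, 20)
  expect_length(intersect(p2$hard_ids, p2$residual_ids), 0)
  # positives never enter the pool
  expect_length(intersect(c(p2$hard_ids, p2$residual_ids),
                          ch$chunk_id[ch$label == "polyp"]), 0)
  expect_error(partition_negatives(ch, "nope"), "not present")
})

test_that("epoch samples are exactly 1:1 with all hard negatives retained", {
  pool <- structure(list(hard_ids = sprintf("h%03d", 1:30),
                         residual_ids = sprintf("r%03d", 1:500)),
                    class = "negative_pool")
  pos <- sprintf("p%03d", 1:100)
  for (epoch in 1:5) {
    es <- draw_epoch_sample(pool, pos, epoch, base_seed = 42)
    expect_length(es$negative_ids, 100)
    expect_true(all(pool$hard_ids %in% es$negative_ids))
    expect_equal(sum(es$negative_ids %in% pool$residual_ids), 70)
    expect_false(any(duplicated(es$negative_ids)))
  }
})

test_that("degenerate sampler regimes warn and stay safe", {
  pool <- structure(list(hard_ids = character(0),
                         residual_ids = sprintf("r%02d", 1:10)),
                    class = "negative_pool")
  expect_warning(es <- draw_epoch_sample(pool, sprintf("p%02d", 1:50), 1, 1),
                 "all negatives")
  expect_length(es$negative_ids, 10)

  pool2 <- structure(list(hard_ids = sprintf("h%02d", 1:25),
                          residual_ids = sprintf("r%02d", 1:40)),
                     class = "negative_pool")
  expect_warning(es2 <- draw_epoch_sample(pool2, sprintf("p%02d", 1:10), 1, 1),
                 "exceeds")
  expect_length(es2$negative_ids, 25)
  expect_setequal(es2$negative_ids, pool2$hard_ids)
})

test_that("draws are reproducible per (seed, epoch) and differ across epochs", {
  pool <- structure(list(hard_ids = sprintf("h%03d", 1:10),
                         residual_ids = sprintf("r%03d", 1:300)),
                    class = "negative_pool")
  pos <- sprintf("p%03d", 1:80)
  a <- draw_epoch_sample(pool, pos, epoch = 3, base_seed = 7)
  b <- draw_epoch_sample(pool, pos, epoch = 3, base_seed = 7)
  expect_identical(a$negative_ids, b$negative_ids)
  cc <- draw_epoch_sample(pool, pos, epoch = 4, base_seed = 7)
  expect_false(identical(sort(a$negative_ids), sort(cc$negative_ids)))
  d <- draw_epoch_sample(pool, pos, epoch = 3, base_seed = 8)
  expect_false(identical(sort(a$negative_ids), sort(d$negative_ids)))

  man <- epoch_sample_manifest(a, pool)
  expect_equal(sum(man$is_hard), 10)
  expect_equal(nrow(man), 160)
})

test_that("balanced class weights follow w_k = N/(K N_k)", {
  w_eq <- class_weights(c(polyp = 25, nonpolyp = 25))
  expect_equal(w_eq$weight, c(1, 1))

  w <- class_weights(c(a = 10, b = 30))
  expect_equal(w$weight, c(40 / 20, 40 / 60))
  expect_equal(w$weight[2], 0.6667, tolerance = 1e-4)

  # full-scale chunk counts of the target application
  w_big <- class_weights(c(polyp = 90096, nonpolyp = 284510))
  expect_equal(w_big$weight[1], 2.0789, tolerance = 1e-4)
  expect_equal(w_big$weight[2], 0.6584, tolerance = 1e-4)

  # sum_k w_k N_k = N exactly, also on random counts
  polypscene:::with_seed(5, {
    for (K in c(2, 3, 5)) {
      n <- sample(1:1000, K)
      cw <- class_weights(setNames(n, paste0("k", seq_len(K))))
      expect_identical(sum(cw$weight * cw$n), as.numeric(sum(n)))
    }
  })
  expect_error(class_weights(c(a = 0, b = 5)), "zero count")
})
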