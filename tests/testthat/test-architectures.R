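# Architecture presets, parameter accounting, softmax and forward contracts.

test_that("stage layouts match the published table", {
  sI <- resnet3d_spec("I")
  expect_equal(sI$conv1_width, 32)
  expect_equal(sI$pool_stride, c(1, 2, 2))
  expect_equal(sI$stages$width, c(32, 64, 128, 256, 512))
  sIV <- resnet3d_spec("IV")
  expect_equal(nrow(sIV$stages), 3)  # conv2..conv4 only
  expect_equal(sIV$conv1_width, 64)
  # wide variants double the narrow stage widths
  sII <- resnet3d_spec("II")
  sIII <- resnet3d_spec("III")
  expect_equal(sII$stages$width, 2 * sI$stages$width[1:4])
  expect_equal(sIV$stages$width, 2 * sIII$stages$width[1:3])
})

test_that("parameter counts are exact for individual layers", {
  m <- build_model(resnet3d_spec("I"), seed = 1, input_dim = c(16, 28, 28))
  lay <- m$layout
  # stem convolution: 3x3x3, 3 -> 32 channels, with bias
  expect_equal(lay$length[lay$kind == "conv_w"][1] +
                 lay$length[lay$kind == "conv_b"][1], 27 * 3 * 32 + 32)
  expect_equal(lay$length[lay$kind == "conv_w"][1] + 32, 2624)
  # classification head: 512 -> 2 affine with bias
  n <- nrow(lay)
  expect_equal(lay$length[n - 1] + lay$length[n], 512 * 2 + 2)
  expect_equal(lay$kind[n], "fc_b")
  # total equals the sum of the layout
  expect_equal(length(m$params), sum(lay$length))
})

test_that("every preset lands near 14 million parameters at full width", {
  for (mid in c("I", "II", "III", "IV")) {
    n <- count_parameters(resnet3d_spec(mid))
    expect_gt(n, 13.5e6)
    expect_lt(n, 14.5e6)
  }
})

test_that("softmax matches direct evaluation and is shift-invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(rep(1.7, 4)), rep(0.25, 4))
  expect_equal(softmax(c(1, 2)), c(0.26894, 0.73106), tolerance = 1e-5)
  polypscene:::with_seed(2, {
    for (i in 1:20) {
      y <- rnorm(sample(2:6, 1), sd = 10)
      q <- softmax(y)
      expect_lt(abs(sum(q) - 1), 1e-6)
      expect_equal(softmax(y + rnorm(1, sd = 50)), q, tolerance = 1e-9)
    }
  })
  ym <- matrix(c(0, 0, 1, 2), 2, byrow = TRUE)
  expect_equal(softmax(ym)[1, ], c(0.5, 0.5))
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("forward pass is well-formed, batched and deterministic", {
  m <- build_model(resnet3d_spec("I", width_scale = 1 / 16), seed = 2)
  zero <- list(as.raw(rep(0, prod(m$input_dim))))
  r <- polypscene:::forward_batch(m, zero)
  expect_equal(dim(r$scores), c(1, 2))
  expect_true(all(is.finite(r$scores)))

  batch <- replicate(3, as.raw(sample(0:255, prod(m$input_dim), TRUE)),
                     simplify = FALSE)
  rb <- polypscene:::forward_batch(m, batch)
  expect_equal(dim(rb$scores), c(3, 2))
  rb2 <- polypscene:::forward_batch(m, batch)
  expect_identical(rb$scores, rb2$scores)

  bad <- list(as.raw(rep(0, 100)))
  expect_error(polypscene:::forward_batch(m, bad), "16,112,112,3")
})

test_that("width-scaled variants preserve topology and run fast", {
  full <- resnet3d_spec("III")
  scaled <- resnet3d_spec("III", width_scale = 1 / 8)
  expect_equal(nrow(scaled$stages), nrow(full$stages))
  expect_equal(scaled$stages$width, full$stages$width / 8)
  m <- build_model(scaled, seed = 1)
  x <- list(as.raw(sample(0:255, prod(m$input_dim), TRUE)))
  t <- system.time(r <- polypscene:::forward_batch(m, x))
  expect_true(all(is.finite(r$scores)))
  expect_lt(t[["elapsed"]], 1)
})

test_that("the C3D-like baseline builds and scores", {
  spec <- resnet3d_spec("c3d_like", width_scale = 1 / 8)
  m <- build_model(spec, seed = 1)
  x <- list(as.raw(sample(0:255, prod(m$input_dim), TRUE)))
  r <- polypscene:::forward_batch(m, x)
  expect_true(all(is.finite(r$scores)))
  # full width sits in the tens of millions, dominated by the FC block
  expect_gt(count_parameters(resnet3d_spec("c3d_like")), 15e6)
})

test_that("predict_scores returns calibrated probabilities per chunk", {
  ch <- fake_chunks(rep(c("polyp", "nonpolyp"), 3))
  m <- build_model(resnet3d_spec("IV", width_scale = 1 / 16), seed = 4)
  out <- predict_scores(m, ch, batch_size = 4)
  expect_equal(nrow(out), 6)
  expect_true(all(out$prob_polyp > 0 & out$prob_polyp < 1))
  expect_equal(out$prob_polyp,
               softmax(cbind(out$score_polyp, out$score_nonpolyp))[, 1])
})
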