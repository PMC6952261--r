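# Fixtures built in code: tiny annotation tables, fake chunk sets (random
# uint8 tensors with controlled labels) and a small cached synthetic dataset
# shared across test files.

ann_from_labels <- function(labels, modality = "white_light") {
  tibble::tibble(frame_index = seq_along(labels) - 1L, label = labels,
                 modality = rep_len(modality, length(labels)))
}

# A chunk_set with arbitrary labels and random tensors; geometry (T, H, W)
# can be shrunk so that forward passes in tests stay fast.
fake_chunks <- function(labels, video_id = "v", chunk_len = 16, size = 112,
                        stride = 8, seed = 1) {
  n <- length(labels)
  tensors <- polypscene:::with_seed(seed, lapply(seq_len(n), function(i) {
    as.raw(sample(0:255, chunk_len * size * size * 3, replace = TRUE))
  }))
  df <- tibble::tibble(
    chunk_id = sprintf("%s#%06d", rep_len(video_id, n), (seq_len(n) - 1) * stride),
    video_id = rep_len(video_id, n),
    start_frame = (seq_len(n) - 1L) * stride,
    label = labels,
    tensor = tensors)
  polypscene:::new_chunk_set(df, chunk_len = chunk_len, stride = stride,
                             size = size, fps = 30)
}

# One small synthetic dataset reused by several test files (generated once
# per test run).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_videos = 6, duration_s = c(10, 12),
                          target_imbalance = 3.16, seed = 11)
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})
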