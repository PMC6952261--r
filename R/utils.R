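# Internal helpers: seeded RNG scoping and deterministic sub-seed derivation.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic integer sub-seed from a base seed and stream indices.
# All arithmetic stays below 2^53 so the result is exact in doubles, and the
# final value fits a 32-bit signed integer.
derive_seed <- function(base, ...) {
  s <- as.double(base) %% 2147483629
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) * 1234567 + 97531) %% 2147483629
  }
  as.integer(s) + 1L
}

# Common label constants and checks.
LABELS <- c("polyp", "nonpolyp")
MODALITIES <- c("white_light", "nbi", "staining")

check_labels <- function(x, what = "label") {
  bad <- setdiff(unique(x), LABELS)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s", what, paste(bad, collapse = ", ")))
  }
  invisible(x)
}
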