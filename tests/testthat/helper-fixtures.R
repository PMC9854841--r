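# Shared fixtures, all built in code at test time.

# A tiny labelled dataset of random RGB images (side >= 32 to satisfy the
# image_sample invariant).
tiny_dataset <- function(n_classes = 2, n_per_class = 3, side = 32, seed = 1) {
  set.seed(seed)
  samples <- list()
  for (cl in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      px <- array(as.double(sample(0:255, side * side * 3, replace = TRUE)),
                  c(side, side, 3))
      samples[[length(samples) + 1L]] <- image_sample(
        px, sprintf("class%02d", cl),
        source_path = sprintf("mem://class%02d/%d", cl, i))
    }
  }
  fossil_dataset(samples)
}

# A flat gray disc on the exact uniform background colour (no sensor noise),
# for background-removal tests.
disc_on_blue <- function(side = 64, radius = 15, gray = 180) {
  px <- array(0, c(side, side, 3))
  px[, , 1] <- 40; px[, , 2] <- 90; px[, , 3] <- 200
  ctr <- (side + 1) / 2
  mask <- (row(px[, , 1]) - ctr)^2 + (col(px[, , 1]) - ctr)^2 <= radius^2
  for (ch in 1:3) {
    pl <- px[, , ch]; pl[mask] <- gray; px[, , ch] <- pl
  }
  list(pixels = px, mask = mask)
}

# Small standardized batch + labels for training tests.
toy_batch <- function(n = 4, side = 32, n_classes = 9, seed = 3) {
  set.seed(seed)
  x <- array(rnorm(side * side * 3 * n), c(side, side, 3, n))
  list(x = x, y = sample(seq_len(n_classes), n, replace = TRUE))
}

# The expensive transfer-benchmark fixture is computed once per test run and
# shared across acceptance test blocks.
.fixture_env <- new.env(parent = emptyenv())

transfer_fixture <- function() {
  if (is.null(.fixture_env$benchmark)) {
    .fixture_env$benchmark <- run_transfer_benchmark(
      seed = 20, include_hog = FALSE,
      checkpoint_path = file.path(tempdir(), "fixture_pre.ckpt"))
  }
  .fixture_env$benchmark
}
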