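net9 <- build_resnet34(9, seed = 1, input_side = 32)

test_that("architecture has the printed depth and block structure", {
  spec <- net9$spec
  expect_equal(count_weighted_layers(spec), 34)
  units <- vapply(spec$stage_plan[-1], `[[`, integer(1), "units")
  expect_equal(unname(units), c(3L, 4L, 6L, 3L))
  expect_equal(count_projection_shortcuts(spec), 3)
  channels <- vapply(spec$stage_plan[-1], `[[`, integer(1), "channels")
  expect_equal(unname(channels), c(64L, 128L, 256L, 512L))
  # head size follows n_classes; fc parameter count from the stage plan
  net2 <- build_resnet34(2, seed = 0, input_side = 32)
  expect_equal(dim(net2$state[["fc.weight"]]), c(2L, 512L))
  expect_equal(length(net2$state[["fc.weight"]]) + length(net2$state[["fc.bias"]]),
               512 * 2 + 2)
  expect_error(build_resnet34(1), "n_classes")
})

test_that("forward produces finite, deterministic logits of the right shape", {
  x <- array(0, c(32, 32, 3, 1))
  l <- forward(net9$state, x)
  expect_equal(dim(l), c(1L, 9L))
  expect_true(all(is.finite(l)))
  set.seed(5)
  xb <- array(rnorm(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  l1 <- forward(net9$state, xb)
  expect_identical(l1, forward(net9$state, xb))
  # identical rows in, identical rows out
  xd <- xb[, , , c(1, 1), drop = FALSE]
  ld <- forward(net9$state, xd)
  expect_equal(ld[1, ], ld[2, ])
  expect_error(forward(net9$state, array(0, c(16, 16, 3, 1))), "32")
})

test_that("forward is permutation-equivariant over the batch axis", {
  set.seed(6)
  xb <- array(rnorm(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  perm <- c(3, 5, 1, 2, 4)
  expect_equal(forward(net9$state, xb)[perm, ],
               forward(net9$state, xb[, , , perm]), tolerance = 1e-10)
})

test_that("a zero residual branch makes a solid-line unit the identity", {
  us <- unit_state(net9$state, "conv2_x", 2)
  us[["conv1.weight"]][] <- 0
  us[["conv2.weight"]][] <- 0
  set.seed(7)
  x <- array(abs(rnorm(8 * 8 * 64 * 2)), c(8, 8, 64, 2))  # post-relu range
  expect_equal(residual_unit_forward(us, x), x, tolerance = 1e-12)
})

test_that("a dashed-line unit halves the grid and doubles the channels", {
  us <- unit_state(net9$state, "conv3_x", 1)
  expect_true("proj.weight" %in% names(us))
  set.seed(7)
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  y <- residual_unit_forward(us, x)
  expect_equal(dim(y), c(4L, 4L, 128L, 1L))
  expect_true(all(is.finite(y)))
  expect_error(residual_unit_forward(us, array(0, c(8, 8, 32, 1))),
               "channel mismatch")
})

test_that("checkpoints round-trip bit-exactly and validate their key set", {
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(net9$state, path)
  re <- load_checkpoint(path)
  expect_identical(names(re), names(net9$state))
  for (k in names(re)) expect_identical(re[[k]], net9$state[[k]])
  expect_equal(attr(re, "n_classes"), 9L)
  expect_equal(attr(re, "input_side"), 32L)
  # corrupt file: clean parse error
  bad <- withr::local_tempfile(fileext = ".ckpt")
  writeLines("garbage", bad)
  expect_error(load_checkpoint(bad), "not a fossilnet checkpoint")
  # truncation: no partial state
  bytes <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".ckpt")
  writeBin(bytes[seq_len(length(bytes) - 1000)], trunc_path)
  expect_error(load_checkpoint(trunc_path), "truncated")
})

test_that("head-size mismatch needs an explicit head replacement", {
  big <- build_resnet34(20, seed = 2, input_side = 32)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(big$state, path)
  expect_error(load_checkpoint(path, expect_classes = 9), "replace_head")
  re <- load_checkpoint(path, expect_classes = 9, replace_head = TRUE, seed = 3)
  expect_equal(dim(re[["fc.weight"]]), c(9L, 512L))
  body_keys <- setdiff(names(re), c("fc.weight", "fc.bias"))
  for (k in body_keys) expect_identical(re[[k]], big$state[[k]])
})

test_that("replace_head changes only the head, reproducibly", {
  r1 <- replace_head(net9$state, 5, seed = 11)
  r2 <- replace_head(net9$state, 5, seed = 11)
  expect_identical(r1[["fc.weight"]], r2[["fc.weight"]])
  expect_equal(dim(r1[["fc.weight"]]), c(5L, 512L))
  body <- setdiff(names(r1), c("fc.weight", "fc.bias"))
  for (k in body) expect_identical(r1[[k]], net9$state[[k]])
  expect_false(identical(r1[["fc.weight"]],
                         replace_head(net9$state, 5, seed = 12)[["fc.weight"]]))
})
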