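test_that("standardization matches direct arithmetic on toy arrays", {
  # channel pattern [0, 2, 0, 2]: mean 1, population sd 1
  px <- array(c(0, 0, 2, 2), c(2, 2, 3))
  st <- standardize(px)
  expect_equal(as.vector(st$values[, , 1]), c(-1, -1, 1, 1))
  expect_equal(st$mean_used, rep(1, 3))
  expect_equal(st$std_used, rep(1, 3))
  # 2x2 toy [[10,20],[30,40]]: mean 25, population sd sqrt(125)
  px2 <- array(c(10, 30, 20, 40), c(2, 2, 3))
  st2 <- standardize(px2)
  expect_equal(as.vector(st2$values[, , 2]),
               c(-1.34164, 0.44721, -0.44721, 1.34164), tolerance = 1e-4)
  # constant image: zero output, degenerate flag
  st3 <- standardize(array(7, c(4, 4, 3)))
  expect_true(all(st3$values == 0))
  expect_true(all(st3$degenerate))
})

test_that("standardized images have zero mean and unit sd per channel", {
  set.seed(8)
  for (i in 1:5) {
    px <- array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3))
    st <- standardize(px)
    for (ch in 1:3) {
      v <- st$values[, , ch]
      expect_lt(abs(mean(v)), 1e-6)
      expect_lt(abs(sqrt(mean(v^2)) - 1), 1e-6)
    }
  }
})

test_that("chroma-key background removal blanks the field, keeps the fossil", {
  d <- disc_on_blue()
  out <- remove_background(d$pixels)
  bg <- !d$mask
  for (ch in 1:3) expect_true(all(out[, , ch][bg] == 0))
  for (ch in 1:3) expect_identical(out[, , ch][d$mask], d$pixels[, , ch][d$mask])
  # no background-coloured pixel: untouched
  gray <- array(128, c(32, 32, 3))
  expect_identical(remove_background(gray), gray)
  # fully background: all black
  blue <- array(rep(c(40, 90, 200), each = 32 * 32), c(32, 32, 3))
  expect_true(all(remove_background(blue) == 0))
})

test_that("affine identities are bit-exact and content can leave the frame", {
  set.seed(2)
  px <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  expect_identical(affine_transform(px, "rotate", 0), px)
  expect_identical(affine_transform(px, "rotate", 360), px)
  expect_identical(affine_transform(px, "scale", 1), px)
  expect_identical(affine_transform(px, "shear", 0), px)
  expect_identical(affine_transform(px, "translate", c(0, 0)), px)
  full <- affine_transform(px, "translate", c(32, 0), fill = 0)
  expect_true(all(full == 0))
  expect_error(affine_transform(px, "rotate", NaN), "finite")
  expect_error(affine_transform(px, "scale", -2), "positive")
})

test_that("90-degree nearest rotation permutes a 2x2 pattern as derived", {
  # hand-derived from the inverse map about the centre (1.5, 1.5):
  # out[1,1] <- in[2,1]; out[1,2] <- in[1,1]; out[2,1] <- in[2,2]; out[2,2] <- in[1,2]
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # in[1,]=1,2; in[2,]=3,4
  out <- affine_transform(px, "rotate", 90, interp = "nearest")
  expect_equal(out[, , 1], matrix(c(3, 4, 1, 2), 2, 2))
})

test_that("gaussian noise is seeded, clipped and sigma-faithful", {
  px <- array(128, c(256, 256, 3))
  expect_identical(add_gaussian_noise(px, 0, 1), px)
  a <- add_gaussian_noise(px, 10, 7)
  b <- add_gaussian_noise(px, 10, 7)
  expect_identical(a, b)
  expect_false(identical(a, add_gaussian_noise(px, 10, 8)))
  expect_lt(abs(mean(a) - 128), 1)
  expect_lt(abs(sd(as.vector(a)) - 10), 1)
  expect_true(min(a) >= 0 && max(a) <= 255)
})

test_that("resize centre-crops to a square then scales", {
  px <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  out <- resize_image(px, 32)
  expect_identical(dim(out), c(32L, 32L, 3L))
  expect_identical(resize_image(px, 64), px)  # already at target
  # 64 x 32 input: crop is rows 17..48, all columns; no rescale needed
  tall <- array(runif(64 * 32 * 3, 0, 255), c(64, 32, 3))
  out2 <- resize_image(tall, 32)
  expect_equal(out2, tall[17:48, , , drop = FALSE])
})

test_that("augmentation preserves labels, balance and determinism", {
  ds <- tiny_dataset(n_classes = 2, n_per_class = 5)
  cfg <- augmentation_config(copies_per_image = 5, seed = 9)
  aug <- augment_dataset(ds, cfg)
  expect_equal(length(aug$samples), 10 * 6)
  expect_true(all(table(aug$manifest$label) == 5 * 6))
  aug2 <- augment_dataset(ds, cfg)
  expect_identical(lapply(aug$samples, `[[`, "pixels"),
                   lapply(aug2$samples, `[[`, "pixels"))
  # all transforms off: copies are identical duplicates
  off <- augmentation_config(translate = FALSE, rotate = FALSE, shear = FALSE,
                             scale = FALSE, gaussian_noise = FALSE,
                             copies_per_image = 2, seed = 1)
  dup <- augment_dataset(ds, off)
  expect_identical(dup$samples[[2]]$pixels, dup$samples[[1]]$pixels)
})
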