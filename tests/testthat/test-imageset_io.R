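test_that("save/load round-trips classes, labels and pixels bit-exactly", {
  ds <- tiny_dataset(n_classes = 3, n_per_class = 2)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  re <- load_dataset(dir)
  expect_identical(re$classes, ds$classes)
  expect_equal(length(re$samples), length(ds$samples))
  for (i in seq_along(ds$samples)) {
    orig <- ds$samples[[i]]
    match_i <- which(vapply(re$samples, function(s)
      identical(s$pixels, orig$pixels), logical(1)))
    expect_length(match_i, 1)
    expect_identical(re$samples[[match_i]]$label, orig$label)
  }
})

test_that("mixed PNG and JPEG inputs load with identical dimensions", {
  dir <- withr::local_tempdir()
  cd <- file.path(dir, "taxonA")
  dir.create(cd, recursive = TRUE)
  set.seed(4)
  px <- array(as.double(sample(0:255, 48 * 48 * 3, replace = TRUE)), c(48, 48, 3))
  fossilnet:::.write_pixels(px, file.path(cd, "a.png"))
  fossilnet:::.write_pixels(px, file.path(cd, "b.jpg"))
  ds <- load_dataset(dir)
  expect_equal(length(ds$samples), 2)
  expect_identical(dim(ds$samples[[1]]$pixels), dim(ds$samples[[2]]$pixels))
  # the lossless copy reproduces the array exactly
  png_i <- grep("\\.png$", vapply(ds$samples, `[[`, "", "source_path"))
  expect_identical(ds$samples[[png_i]]$pixels, px)
})

test_that("degenerate roots and unreadable files are handled", {
  empty <- withr::local_tempdir()
  expect_error(load_dataset(empty), "no classes found")
  dir <- withr::local_tempdir()
  cd <- file.path(dir, "cls")
  dir.create(cd)
  fossilnet:::.write_pixels(array(128, c(32, 32, 3)), file.path(cd, "ok.png"))
  writeLines("not an image", file.path(cd, "bad.png"))
  expect_warning(ds <- load_dataset(dir), "unreadable")
  expect_equal(length(ds$samples), 1)
  expect_equal(attr(ds, "skipped"), file.path(cd, "bad.png"))
})

test_that("split is balanced, disjoint and deterministic across seeds", {
  ds <- tiny_dataset(n_classes = 3, n_per_class = 6)
  for (seed in 1:4) {
    for (test_n in c(1, 2)) {
      sp <- make_split(ds, test_n, seed)
      expect_true(all(table(sp$test$manifest$label) == test_n))
      expect_true(all(table(sp$train$manifest$label) == 6 - test_n))
      expect_length(intersect(sp$test$manifest$path, sp$train$manifest$path), 0)
      expect_setequal(c(sp$test$manifest$path, sp$train$manifest$path),
                      ds$manifest$path)
      sp2 <- make_split(ds, test_n, seed)
      expect_identical(sp$test$manifest, sp2$test$manifest)
    }
  }
  # differing seeds give a different membership somewhere
  memb <- vapply(1:6, function(s)
    paste(make_split(ds, 2, s)$test$manifest$path, collapse = ";"), "")
  expect_gt(length(unique(memb)), 1)
})

test_that("split refuses a class with too few samples, naming it", {
  ds <- tiny_dataset(n_classes = 2, n_per_class = 3)
  expect_error(make_split(ds, 3, 1), "class01")
})

test_that("training groups are balanced, independent and seed-deterministic", {
  ds <- tiny_dataset(n_classes = 3, n_per_class = 8)
  sizes <- c(1, 2, 4)
  plans <- sample_training_groups(ds, sizes, n_groups = 10, seed = 5)
  expect_length(plans, 30)
  for (pl in plans) {
    expect_s3_class(pl, "sampling_plan")
    expect_true(all(lengths(pl$indices) == pl$per_class_train_n))
    sub <- realize_plan(ds, pl)
    expect_true(all(table(sub$manifest$label) == pl$per_class_train_n))
  }
  plans2 <- sample_training_groups(ds, sizes, n_groups = 10, seed = 5)
  expect_identical(plans, plans2)
  # groups of the same size differ in membership (8 choose 2 leaves room)
  same_size <- Filter(function(p) p$per_class_train_n == 2, plans)
  keys <- vapply(same_size, function(p)
    paste(unlist(p$indices), collapse = ","), "")
  expect_gt(length(unique(keys)), 1)
  expect_error(sample_training_groups(ds, c(1, 9), 2, 1), "exceeds")
})

test_that("a 3-sample class enumerates its draws as expected", {
  # with 3 samples per class and groups of 2, only 3 subsets exist; over
  # many groups all 3 must appear and repeats are inevitable
  ds <- tiny_dataset(n_classes = 1, n_per_class = 3)
  plans <- sample_training_groups(ds, 2, n_groups = 30, seed = 2)
  keys <- vapply(plans, function(p) paste(sort(unlist(p$indices)), collapse = "-"), "")
  expect_setequal(unique(keys), c("1-2", "1-3", "2-3"))
})
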