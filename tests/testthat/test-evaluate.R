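# independent brute-force tally used as the metrics oracle
brute_confusion <- function(truth, pred, k) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

brute_prf <- function(cm, k) {
  tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

test_that("confusion matrix counts match a brute-force pairwise tally", {
  expect_equal(unclass(confusion_matrix(rep(1:3, each = 2), rep(1:3, each = 2), 3)),
               diag(c(2L, 2L, 2L)), ignore_attr = TRUE)
  cm <- confusion_matrix(1, 2, 3)
  expect_equal(cm[1, 2], 1L)
  expect_equal(sum(cm), 1L)
  set.seed(10)
  for (rep in 1:5) {
    truth <- sample(1:4, 100, TRUE)
    pred <- sample(1:4, 100, TRUE)
    expect_equal(unclass(confusion_matrix(truth, pred, 4)),
                 brute_confusion(truth, pred, 4), ignore_attr = TRUE)
  }
  expect_error(confusion_matrix(1:3, 1:2, 3), "length")
  expect_error(confusion_matrix(1:3, c(1, 2, 9), 3), "range")
})

test_that("precision, recall and F1 follow their defining formulas", {
  # TP=8, FP=2, FN=4
  cm <- matrix(c(8L, 2L, 4L, 0L), 2, 2)
  m <- precision_recall_f1(cm, 1)
  expect_equal(unname(m["precision"]), 0.8, ignore_attr = TRUE)
  expect_equal(unname(m["recall"]), 0.66667, tolerance = 1e-4)
  expect_equal(unname(m["f1"]), 0.72727, tolerance = 1e-4)
  # perfect class
  perfect <- precision_recall_f1(diag(c(5L, 3L)), 1)
  expect_equal(unname(perfect), c(1, 1, 1), ignore_attr = TRUE)
  expect_false(attr(perfect, "zero_division"))
  # TP = 0 with FP, FN > 0: all zero, flagged
  cm0 <- matrix(c(0L, 3L, 2L, 5L), 2, 2)
  z <- precision_recall_f1(cm0, 1)
  expect_equal(unname(z), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(z, "zero_division"))
})

test_that("metric functions agree with the oracle on 1,000 random matrices", {
  set.seed(11)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    cls <- sample(k, 1)
    expect_equal(unname(precision_recall_f1(cm, cls)), brute_prf(cm, cls),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("macro averages are unweighted class means", {
  df <- data.frame(precision = c(1, 0.5), recall = c(1, 0.5), f1 = c(1, 0.5))
  expect_equal(unname(macro_average(df)), c(0.75, 0.75, 0.75))
  same <- data.frame(precision = rep(0.4, 3), recall = rep(0.4, 3), f1 = rep(0.4, 3))
  expect_equal(unname(macro_average(same)), rep(0.4, 3))
  set.seed(12)
  rnd <- data.frame(precision = runif(7), recall = runif(7), f1 = runif(7))
  expect_equal(unname(macro_average(rnd)),
               unname(colMeans(rnd)))
})

test_that("micro precision equals micro recall equals accuracy; misjudgment bounded", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4), k, k)
    tp <- diag(cm)
    micro_p <- sum(tp) / sum(colSums(cm))
    micro_r <- sum(tp) / sum(rowSums(cm))
    rep <- metrics_report(cm)
    expect_equal(micro_p, micro_r)
    expect_equal(rep$accuracy, micro_p)
    expect_equal(rep$misjudgment_rate, 1 - sum(diag(cm)) / sum(cm))
    expect_gte(rep$misjudgment_rate, 0)
    expect_lte(rep$misjudgment_rate, 1)
    # F1 lies between precision and recall where both are defined
    ok <- rep$per_class$precision + rep$per_class$recall > 0
    expect_true(all(rep$per_class$f1[ok] >=
                      pmin(rep$per_class$precision, rep$per_class$recall)[ok] - 1e-12))
    expect_true(all(rep$per_class$f1[ok] <=
                      pmax(rep$per_class$precision, rep$per_class$recall)[ok] + 1e-12))
  }
})

test_that("run_experiment books the full strategy x size x group grid", {
  ds <- generate_benchmark(6, side = 128, seed = 31)
  cfg <- experiment_config(test_n_per_class = 2, input_side = 32, epochs = 1)
  res <- run_experiment(ds, NULL, strategies = "scratch", sizes = c(1, 2),
                        n_groups = 2, cfg = cfg, seed = 17)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$runs), 4)
  expect_equal(nrow(res$aggregate), 2)
  expect_true(all(res$aggregate$n_groups == 2))
  expect_equal(nrow(res$per_class), 4 * 9)
  expect_true(all(res$runs$macro_f1 >= 0 & res$runs$macro_f1 <= 1))
  res2 <- run_experiment(ds, NULL, strategies = "scratch", sizes = c(1, 2),
                         n_groups = 2, cfg = cfg, seed = 17)
  expect_identical(res$aggregate, res2$aggregate)
  expect_error(run_experiment(ds, NULL, strategies = "scratch", sizes = 10,
                              n_groups = 1, cfg = cfg, seed = 1), "infeasible")
})

test_that("the baseline arm plugs into the same splits and metrics", {
  ds <- generate_benchmark(5, side = 128, seed = 41)
  cfg <- experiment_config(test_n_per_class = 2, input_side = 32)
  res <- run_experiment(ds, NULL, strategies = "hog_svm", sizes = c(1, 3),
                        n_groups = 2, cfg = cfg, seed = 19,
                        hog_cfg = hog_config(image_side = 32))
  expect_equal(nrow(res$runs), 4)
  expect_true(all(is.finite(res$runs$macro_f1)))
})
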