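test_that("freeze plans realize the strategy table", {
  tf <- make_freeze_plan("TF")
  expect_equal(unname(tf[c("conv1", "conv2_x", "conv3_x", "conv4_x", "conv5_x", "fc")]),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE), ignore_attr = TRUE)
  ta <- make_freeze_plan("TA")
  expect_true(all(ta))
  ts <- make_freeze_plan("TS", "conv3_x")
  expect_equal(unname(ts), c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
               ignore_attr = TRUE)
  ts5 <- make_freeze_plan("TS", "conv5_x")
  expect_equal(sum(ts5), 2)  # conv5_x + fc
  expect_error(make_freeze_plan("TS"), "retrain_from")
  expect_error(make_freeze_plan("TS", "conv1"), "retrain_from")
})

test_that("trainable-parameter counts are strictly monotone across strategies", {
  st <- build_resnet34(9, seed = 0, input_side = 32)$state
  plans <- list(make_freeze_plan("TF"),
                make_freeze_plan("TS", "conv5_x"),
                make_freeze_plan("TS", "conv4_x"),
                make_freeze_plan("TS", "conv3_x"),
                make_freeze_plan("TS", "conv2_x"),
                make_freeze_plan("TA"))
  counts <- vapply(plans, trainable_parameter_count, numeric(1), state = st)
  expect_true(all(diff(counts) > 0))
  expect_equal(counts[1], 512 * 9 + 9)  # TF trains only the head
})

test_that("frozen tensors are bit-identical after training, trainable ones move", {
  tb <- toy_batch(n = 4)
  cfg <- train_config(epochs = 1, seed = 2)
  st0 <- build_resnet34(9, seed = 4, input_side = 32)$state
  strategies <- list(TF = make_freeze_plan("TF"),
                     TS3 = make_freeze_plan("TS", "conv3_x"),
                     TS5 = make_freeze_plan("TS", "conv5_x"),
                     TA = make_freeze_plan("TA"))
  for (nm in names(strategies)) {
    plan <- strategies[[nm]]
    fit <- train(st0, plan, tb$x, tb$y, cfg)
    frozen_blocks <- names(plan)[!plan]
    frozen_keys <- unlist(lapply(frozen_blocks, fossilnet:::.block_all_keys,
                                 state = st0))
    for (k in frozen_keys)
      expect_identical(fit$state[[k]], st0[[k]],
                       label = paste(nm, k, "frozen tensor"))
    train_keys <- unlist(lapply(names(plan)[plan], fossilnet:::.block_param_keys,
                                state = st0))
    moved <- vapply(train_keys, function(k)
      !identical(fit$state[[k]], st0[[k]]), logical(1))
    expect_true(any(moved), label = paste(nm, "some trainable tensor moved"))
    expect_true(all(is.finite(fit$history$loss)))
  }
})

test_that("zero learning rate changes no tensor at all", {
  tb <- toy_batch(n = 4)
  st0 <- build_resnet34(9, seed = 4, input_side = 32)$state
  fit <- train(st0, make_freeze_plan("TA"), tb$x, tb$y,
               train_config(learning_rate = 0, epochs = 2, seed = 1))
  for (k in names(st0)) expect_identical(fit$state[[k]], st0[[k]])
})

test_that("training is deterministic and the cached-feature path is exact", {
  tb <- toy_batch(n = 5)
  st0 <- build_resnet34(9, seed = 4, input_side = 32)$state
  cfg <- train_config(epochs = 2, seed = 7)
  plan <- make_freeze_plan("TS", "conv5_x")
  f1 <- train(st0, plan, tb$x, tb$y, cfg)
  f2 <- train(st0, plan, tb$x, tb$y, cfg)
  expect_identical(f1$state, f2$state)
  expect_identical(f1$history, f2$history)
  # frozen-prefix features fed back in give the same trained model
  env <- new.env(); env$state <- st0
  feats <- fossilnet:::.forward_convs(env, tb$x,
    c("conv1", "conv2_x", "conv3_x", "conv4_x"), training = FALSE)$y
  f3 <- train(st0, plan, feats, tb$y, cfg, x_is_output_of = "conv4_x")
  for (k in names(st0)) expect_equal(f3$state[[k]], f1$state[[k]], tolerance = 1e-12)
  # and cached-feature prediction matches the full forward pass
  p_full <- predict(f1$state, tb$x)
  p_feat <- fossilnet:::.predict_from_features(f3$state, feats, "conv4_x")
  expect_equal(p_feat$probs, p_full$probs, tolerance = 1e-10)
  expect_identical(p_feat$labels, p_full$labels)
})

test_that("training rejects empty or inconsistent inputs", {
  st0 <- build_resnet34(9, seed = 4, input_side = 32)$state
  tb <- toy_batch(n = 3)
  expect_error(train(st0, make_freeze_plan("TF"),
                     array(0, c(32, 32, 3, 0)), integer(0)), "empty")
  expect_error(train(st0, make_freeze_plan("TF"), tb$x, c(1, 2)), "sample count")
  expect_error(train(st0, make_freeze_plan("TF"), tb$x, c(1, 2, 99)), "range")
})

test_that("prediction breaks ties toward the lowest class and sums to one", {
  st <- build_resnet34(9, seed = 4, input_side = 32)$state
  st[["fc.weight"]][] <- 0
  st[["fc.bias"]][] <- 0   # all logits equal -> tie
  tb <- toy_batch(n = 3)
  p <- predict(st, tb$x)
  expect_true(all(p$labels == 1L))
  expect_equal(rowSums(p$probs), rep(1, 3), tolerance = 1e-6)
  # batch order does not matter
  st2 <- build_resnet34(9, seed = 5, input_side = 32)$state
  p1 <- predict(st2, tb$x)
  perm <- c(3, 1, 2)
  p2 <- predict(st2, tb$x[, , , perm])
  expect_identical(p1$labels[perm], p2$labels)
})

test_that("the full network overfits a tiny separable two-class set", {
  specs <- taxon_specs()[c("sphere", "cone_tube")]
  samples <- list()
  for (f in 1:2) for (i in 1:3) {
    s <- generate_taxon_image(specs[[f]], 64, seed = 50 * f + i)
    s$source_path <- paste0(s$source_path, "#", i)
    samples[[length(samples) + 1L]] <- s
  }
  ds <- fossil_dataset(samples)
  tens <- dataset_tensor(ds, 32)
  net <- build_resnet34(2, seed = 1, input_side = 32)
  fit <- train(net$state, make_freeze_plan("TA"), tens$x, tens$y,
               train_config(learning_rate = 1e-3, epochs = 40, seed = 1))
  acc <- mean(predict(fit$state, tens$x)$labels == tens$y)
  expect_equal(acc, 1)
})
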