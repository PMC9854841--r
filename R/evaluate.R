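# Confusion-matrix evaluation and the repeated-subsampling experiment
# protocol: for each (strategy, training size, group) a fresh model is
# fine-tuned on a balanced group and scored on the single fixed test set;
# scores are averaged over groups.

#' Confusion matrix from paired label vectors
#'
#' @param true_labels,predicted_labels integer class indices (1-based),
#'   equal length.
#' @param n_classes number of classes.
#' @return `confusion_matrix`: an `n_classes x n_classes` integer matrix,
#'   `counts[i, j]` = number of samples with true class `i` predicted as
#'   class `j`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (length(true_labels) &&
      (min(true_labels, predicted_labels) < 1 ||
       max(true_labels, predicted_labels) > n_classes))
    stop("labels out of range 1..", n_classes)
  cm <- matrix(tabulate((predicted_labels - 1L) * n_classes + true_labels,
                        nbins = n_classes * n_classes),
               n_classes, n_classes)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Any 0/0 is
#' defined as 0 and flagged via the `zero_division` attribute.
#'
#' @param cm a [confusion_matrix()].
#' @param class_index class to score (1-based).
#' @return named numeric `c(precision, recall, f1)` with attribute
#'   `zero_division` (logical).
#' @export
precision_recall_f1 <- function(cm, class_index) {
  k <- class_index
  stopifnot(k >= 1, k <= nrow(cm))
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  zdiv <- FALSE
  div0 <- function(num, den) {
    if (den == 0) { zdiv <<- TRUE; 0 } else num / den
  }
  p <- div0(tp, tp + fp)
  r <- div0(tp, tp + fn)
  f1 <- div0(2 * p * r, p + r)
  structure(c(precision = p, recall = r, f1 = f1), zero_division = zdiv)
}

#' Full metrics report for one evaluation run
#'
#' @param cm a [confusion_matrix()].
#' @param classes optional class names for the per-class table.
#' @return `metrics_report`: list with `per_class` (data frame of
#'   precision, recall, f1), `macro_precision`, `macro_recall`, `macro_f1`
#'   (unweighted class means), `accuracy` and `misjudgment_rate`
#'   (`1 - accuracy`).
#' @export
metrics_report <- function(cm, classes = NULL) {
  nc <- nrow(cm)
  per <- t(vapply(seq_len(nc), function(k) precision_recall_f1(cm, k),
                  numeric(3)))
  per <- as.data.frame(per)
  names(per) <- c("precision", "recall", "f1")
  per$class <- if (is.null(classes)) as.character(seq_len(nc)) else classes
  per <- per[, c("class", "precision", "recall", "f1")]
  total <- sum(cm)
  acc <- if (total > 0) sum(diag(cm)) / total else 0
  structure(list(per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 accuracy = acc,
                 misjudgment_rate = 1 - acc,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> macro P %.4f R %.4f F1 %.4f | misjudgment %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1, x$misjudgment_rate))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Unweighted macro average of per-class scores
#'
#' @param reports a per-class data frame with columns precision/recall/f1
#'   (as in a `metrics_report`), or a list of length-3 per-class score
#'   vectors.
#' @return named numeric `c(macro_precision, macro_recall, macro_f1)`.
#' @export
macro_average <- function(reports) {
  if (is.data.frame(reports)) {
    m <- colMeans(reports[, c("precision", "recall", "f1")])
  } else {
    m <- colMeans(do.call(rbind, lapply(reports, function(r) r[1:3])))
  }
  stats::setNames(as.numeric(m), c("macro_precision", "macro_recall", "macro_f1"))
}

#' Experiment configuration for the training-size sweep
#'
#' @param test_n_per_class size of the fixed balanced test set per class
#'   (default 100).
#' @param input_side network input side for the experiment.
#' @param epochs,learning_rate,batch_size fine-tuning settings (see
#'   [train_config()]).
#' @param augment optional [augmentation_config()] applied to each training
#'   group (never to the test set); `NULL` disables augmentation.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(test_n_per_class = 100, input_side = 224,
                              epochs = 30, learning_rate = 1e-4,
                              batch_size = 16, augment = NULL) {
  structure(list(test_n_per_class = as.integer(test_n_per_class),
                 input_side = as.integer(input_side),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), augment = augment),
            class = "experiment_config")
}

# Parse "TF" / "TA" / "TS:conv3_x" / "scratch" / "hog_svm".
.parse_strategy <- function(s) {
  if (s %in% c("TF", "TA", "scratch", "hog_svm"))
    return(list(name = s, type = s, retrain_from = NULL))
  if (grepl("^TS:", s))
    return(list(name = s, type = "TS", retrain_from = sub("^TS:", "", s)))
  stop("unknown strategy: ", s)
}

# Frozen prefix (conv blocks) of a plan, possibly empty.
.frozen_prefix <- function(plan) {
  conv_blocks <- setdiff(.block_order, "fc")
  ft <- names(plan)[plan][1]
  if (ft == "conv1") return(character(0))
  if (ft == "fc") return(conv_blocks)
  conv_blocks[seq_len(match(ft, conv_blocks) - 1L)]
}

#' Run the repeated-subsampling transfer experiment
#'
#' Implements the evaluation protocol: split off a fixed balanced test set,
#' draw `n_groups` independent balanced training groups for every requested
#' per-class size, and for each (strategy, size, group) fine-tune a fresh
#' model (pretrained body + newly initialised head, frozen per the
#' strategy) and score it on the test set. Group scores are averaged per
#' (strategy, size).
#'
#' Strategies are given as strings: `"TF"`, `"TA"`, `"TS:<block>"` (e.g.
#' `"TS:conv3_x"`), `"scratch"` (randomly initialised network, all layers
#' trained -- the no-transfer reference), and `"hog_svm"` (the
#' HOG-feature + SVM machine-learning baseline, which reuses the identical
#' splits and metrics).
#'
#' For frozen-prefix strategies the forward pass through the frozen blocks
#' is computed once per strategy and reused across groups and sizes; this
#' is an exact algebraic factorisation of the naive per-run computation,
#' not an approximation.
#'
#' @param dataset a `fossil_dataset` containing all taxa.
#' @param pretrained_ckpt path to a checkpoint from [save_checkpoint()]
#'   (needed by TF/TS/TA; ignored by scratch and hog_svm).
#' @param strategies character vector of strategy strings.
#' @param sizes integer vector of per-class training sizes.
#' @param n_groups independent groups per size.
#' @param cfg an [experiment_config()].
#' @param seed master seed: split, groups, head draws and training shuffles
#'   all derive from it.
#' @param hog_cfg a [hog_config()] for the `hog_svm` strategy.
#' @return `experiment_result`: list with `runs` (long data frame: strategy,
#'   size, group, macro_precision, macro_recall, macro_f1,
#'   misjudgment_rate), `per_class` (long data frame with per-taxon P/R/F1
#'   per run), `aggregate` (mean and sd of macro F1 per strategy x size over
#'   exactly `n_groups` entries), and `config`.
#' @export
run_experiment <- function(dataset, pretrained_ckpt = NULL,
                           strategies = "TS:conv3_x",
                           sizes = c(1, 3, 5, 10, 50, 100, 200),
                           n_groups = 10, cfg = experiment_config(), seed = 0,
                           hog_cfg = NULL) {
  split <- make_split(dataset, cfg$test_n_per_class, seed)
  pool_n <- min(table(split$train$manifest$label))
  if (max(sizes) > pool_n)
    stop("infeasible size ", max(sizes), ": training pool has only ",
         pool_n, " per class")
  plans <- sample_training_groups(split$train, sizes, n_groups, seed + 1L)
  nc <- length(dataset$classes)
  side <- cfg$input_side

  needs_net <- any(vapply(strategies, function(s)
    .parse_strategy(s)$type != "hog_svm", logical(1)))
  test_t <- if (needs_net) dataset_tensor(split$test, side)
  pool_t <- if (needs_net && is.null(cfg$augment)) dataset_tensor(split$train, side)
  tcfg <- train_config(learning_rate = cfg$learning_rate,
                       batch_size = cfg$batch_size, epochs = cfg$epochs)

  run_rows <- list(); per_rows <- list()
  for (s in strategies) {
    ps <- .parse_strategy(s)
    if (ps$type == "hog_svm") {
      res <- .run_hog_arm(split, plans, cfg, hog_cfg, seed)
    } else {
      res <- .run_net_arm(split, plans, ps, pretrained_ckpt, test_t, pool_t,
                          tcfg, cfg, seed)
    }
    for (r in res) {
      rep <- r$report
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        strategy = s, size = r$size, group = r$group,
        macro_precision = rep$macro_precision, macro_recall = rep$macro_recall,
        macro_f1 = rep$macro_f1, misjudgment_rate = rep$misjudgment_rate)
      pc <- rep$per_class
      pc$strategy <- s; pc$size <- r$size; pc$group <- r$group
      per_rows[[length(per_rows) + 1L]] <- pc
    }
  }
  runs <- do.call(rbind, run_rows)
  per_class <- do.call(rbind, per_rows)
  agg <- do.call(rbind, lapply(split(runs, list(runs$strategy, runs$size),
                                     drop = TRUE), function(g) {
    data.frame(strategy = g$strategy[1], size = g$size[1],
               n_groups = nrow(g),
               mean_macro_f1 = mean(g$macro_f1), sd_macro_f1 = stats::sd(g$macro_f1),
               mean_macro_precision = mean(g$macro_precision),
               mean_macro_recall = mean(g$macro_recall),
               mean_misjudgment_rate = mean(g$misjudgment_rate))
  }))
  agg <- agg[order(agg$strategy, agg$size), ]
  rownames(agg) <- NULL
  structure(list(runs = runs, per_class = per_class, aggregate = agg,
                 config = cfg, classes = dataset$classes, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

# Network arm of the experiment. Frozen-prefix features of the training
# pool and the test set are computed once per strategy and sliced per run.
.run_net_arm <- function(split, plans, ps, ckpt, test_t, pool_t, tcfg, cfg, seed) {
  nc <- length(split$train$classes)
  augmenting <- !is.null(cfg$augment)
  if (ps$type == "scratch") {
    plan <- make_freeze_plan("TA")
    base <- NULL
  } else {
    if (is.null(ckpt)) stop("strategy ", ps$name, " needs a pretrained checkpoint")
    plan <- switch(ps$type, TF = make_freeze_plan("TF"),
                   TA = make_freeze_plan("TA"),
                   TS = make_freeze_plan("TS", ps$retrain_from))
    base <- load_checkpoint(ckpt, expect_classes = nc, replace_head = TRUE,
                            seed = seed)
  }
  prefix <- if (is.null(base)) character(0) else .frozen_prefix(plan)
  cache_ok <- length(prefix) > 0L && !augmenting
  if (cache_ok) {
    env <- new.env(parent = emptyenv()); env$state <- base
    pool_f <- .forward_convs(env, pool_t$x, prefix, training = FALSE)$y
    test_f <- .forward_convs(env, test_t$x, prefix, training = FALSE)$y
    last_frozen <- prefix[length(prefix)]
  }
  lapply(plans, function(pl) {
    run_seed <- seed + 7L * pl$seed %% 1000003L
    st <- if (is.null(base))
      build_resnet34(nc, seed = run_seed, input_side = cfg$input_side)$state
    else replace_head(base, nc, seed = run_seed)
    rcfg <- tcfg; rcfg$seed <- run_seed
    if (cache_ok) {
      idx <- unlist(pl$indices, use.names = FALSE)
      fit <- train(st, plan, pool_f[, , , idx, drop = FALSE],
                   pool_t$y[idx], rcfg, x_is_output_of = last_frozen)
      pred <- .predict_from_features(fit$state, test_f, last_frozen)
    } else {
      tr_ds <- realize_plan(split$train, pl)
      if (augmenting) tr_ds <- augment_dataset(tr_ds, cfg$augment)
      tr <- dataset_tensor(tr_ds, cfg$input_side)
      fit <- train(st, plan, tr$x, tr$y, rcfg)
      pred <- predict(fit$state, test_t$x)
    }
    cm <- confusion_matrix(test_t$y, pred$labels, nc)
    list(size = pl$per_class_train_n, group = pl$group_index,
         report = metrics_report(cm, split$train$classes))
  })
}

# Inference from cached frozen-prefix features: run the remaining conv
# blocks and the head.
.predict_from_features <- function(state, feats, last_frozen) {
  conv_blocks <- setdiff(.block_order, "fc")
  i <- match(last_frozen, conv_blocks)
  env <- new.env(parent = emptyenv()); env$state <- state
  y <- if (i < length(conv_blocks))
    .forward_convs(env, feats, conv_blocks[seq(i + 1L, length(conv_blocks))],
                   training = FALSE)$y
  else feats
  probs <- .softmax(.head_fwd(state, .gap(y)))
  list(labels = max.col(probs, ties.method = "first"), probs = probs)
}

# HOG + SVM arm: identical splits and metrics, features computed once on
# the pool and test set.
.run_hog_arm <- function(split, plans, cfg, hog_cfg, seed) {
  if (is.null(hog_cfg)) hog_cfg <- hog_config(image_side = cfg$input_side)
  nc <- length(split$train$classes)
  pool_f <- .hog_matrix(split$train, hog_cfg)
  test_f <- .hog_matrix(split$test, hog_cfg)
  pool_y <- match(vapply(split$train$samples, function(s) s$label, character(1)),
                  split$train$classes)
  test_y <- match(vapply(split$test$samples, function(s) s$label, character(1)),
                  split$test$classes)
  lapply(plans, function(pl) {
    idx <- unlist(pl$indices, use.names = FALSE)
    clf <- train_svm_baseline(pool_f[idx, , drop = FALSE], pool_y[idx],
                              params = list(seed = seed + pl$seed))
    pred <- predict(clf, test_f)
    cm <- confusion_matrix(test_y, pred, nc)
    list(size = pl$per_class_train_n, group = pl$group_index,
         report = metrics_report(cm, split$train$classes))
  })
}
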