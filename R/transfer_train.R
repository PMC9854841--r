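# Layer-freezing transfer strategies and the training loop. A freeze plan
# assigns each block of the backbone to frozen (parameters retained from the
# pretrained model) or trainable (retrained on target data). All supported
# strategies freeze a prefix of the block order and retrain the remaining
# suffix, which lets the training loop push the data through the frozen
# prefix exactly once and iterate only over the trainable suffix.

#' Freeze plan for a fine-tuning strategy
#'
#' `TF` retrains only the fully connected head; `TA` retrains everything;
#' `TS` freezes the low "generic feature" stages and retrains from
#' `retrain_from` onward (plus the head). The head is always trainable and
#' the trainable blocks always form a contiguous suffix of
#' `conv1, conv2_x, conv3_x, conv4_x, conv5_x, fc`.
#'
#' @param strategy `"TF"`, `"TS"` or `"TA"`.
#' @param retrain_from for `TS`: first retrained block, one of `"conv2_x"`,
#'   `"conv3_x"`, `"conv4_x"`, `"conv5_x"`.
#' @return object of class `freeze_plan`: named logical vector over blocks,
#'   `TRUE` = trainable.
#' @export
make_freeze_plan <- function(strategy = c("TF", "TS", "TA"), retrain_from = NULL) {
  strategy <- match.arg(strategy)
  trainable <- stats::setNames(rep(FALSE, length(.block_order)), .block_order)
  trainable["fc"] <- TRUE
  if (strategy == "TA") trainable[] <- TRUE
  if (strategy == "TS") {
    if (is.null(retrain_from) ||
        !retrain_from %in% c("conv2_x", "conv3_x", "conv4_x", "conv5_x"))
      stop("TS needs retrain_from in conv2_x..conv5_x")
    from <- match(retrain_from, .block_order)
    trainable[seq(from, length(.block_order))] <- TRUE
  }
  structure(trainable, class = "freeze_plan", strategy = strategy,
            retrain_from = retrain_from)
}

#' @export
print.freeze_plan <- function(x, ...) {
  marks <- ifelse(x, "retrain", "frozen")
  cat(sprintf("<freeze_plan> %s\n", attr(x, "strategy")))
  for (b in names(x)) cat(sprintf("  %-8s %s\n", b, marks[b]))
  invisible(x)
}

# Learnable parameter keys (conv weights, bn scale/shift, fc) for a block.
.block_param_keys <- function(state, block) {
  keys <- names(state)
  if (block == "fc") return(c("fc.weight", "fc.bias"))
  keys <- keys[startsWith(keys, paste0(block, "."))]
  keys[grepl("\\.(weight|scale|shift)$", keys)]
}

# Every tensor key belonging to a block, running statistics included.
.block_all_keys <- function(state, block) {
  if (block == "fc") return(c("fc.weight", "fc.bias"))
  names(state)[startsWith(names(state), paste0(block, "."))]
}

#' Count trainable parameters under a freeze plan
#'
#' Counts convolution weights, batch-norm scales/shifts and the head in
#' trainable blocks; frozen blocks and running statistics contribute
#' nothing. Strictly monotone across the strategy ladder
#' `TF < TS(conv5_x) < TS(conv4_x) < TS(conv3_x) < TS(conv2_x) < TA`.
#'
#' @param state a `model_state`.
#' @param plan a `freeze_plan`.
#' @return integer parameter count.
#' @export
trainable_parameter_count <- function(state, plan) {
  keys <- unlist(lapply(names(plan)[plan], .block_param_keys, state = state))
  sum(vapply(state[keys], length, numeric(1)))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size minibatch size (default 16); the last incomplete batch
#'   is kept, so sets smaller than one batch still train.
#' @param epochs passes over the training set (default 30).
#' @param seed seed for shuffling order (and any other training randomness).
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16, epochs = 30,
                         seed = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Convert a dataset into a standardized image tensor
#'
#' Resizes every sample to `side x side` (centre square crop + bilinear),
#' standardizes it per image and channel, and stacks the results into the
#' 4-D batch array the network consumes.
#'
#' @param ds a `fossil_dataset`.
#' @param side network input side.
#' @return `list(x = side x side x 3 x N array, y = integer class indices
#'   (1-based, into `classes`), classes = ds$classes)`.
#' @export
dataset_tensor <- function(ds, side) {
  n <- length(ds$samples)
  x <- array(0, c(side, side, 3L, n))
  for (i in seq_len(n)) {
    px <- resize_image(ds$samples[[i]]$pixels, side)
    x[, , , i] <- standardize(px)$values
  }
  y <- match(vapply(ds$samples, function(s) s$label, character(1)), ds$classes)
  list(x = x, y = y, classes = ds$classes)
}

# --- backward pass through the trainable suffix -----------------------------

.acc_grad <- function(g, key, val) {
  g[[key]] <- if (is.null(g[[key]])) val else g[[key]] + val
  g
}

.bn_bwd <- function(env, bnp, cache, dy) {
  r <- nn_bn_backward(cache[[paste0(bnp, ".in")]], dy, env$state[[paste0(bnp, ".scale")]],
                      cache[[paste0(bnp, ".mean")]], cache[[paste0(bnp, ".invstd")]])
  env$g <- .acc_grad(env$g, paste0(bnp, ".scale"), r$dgamma)
  env$g <- .acc_grad(env$g, paste0(bnp, ".shift"), r$dbeta)
  r$dx
}

.unit_bwd <- function(env, prefix, cache, dy, need_dx) {
  dpre <- dy * (cache$y > 0)
  da2 <- .bn_bwd(env, paste0(prefix, ".bn2"), cache, dpre)
  c2 <- nn_conv_backward(cache$h, env$state[[paste0(prefix, ".conv2.weight")]],
                         da2, 1L, 1L, TRUE)
  env$g <- .acc_grad(env$g, paste0(prefix, ".conv2.weight"), c2$dw)
  dh <- c2$dx * (cache$h > 0)
  da1 <- .bn_bwd(env, paste0(prefix, ".bn1"), cache, dh)
  c1 <- nn_conv_backward(cache$x, env$state[[paste0(prefix, ".conv1.weight")]],
                         da1, cache$stride, 1L, need_dx)
  env$g <- .acc_grad(env$g, paste0(prefix, ".conv1.weight"), c1$dw)
  dx <- if (need_dx) c1$dx
  if (cache$has_proj) {
    dp <- .bn_bwd(env, paste0(prefix, ".projbn"), cache, dpre)
    cp <- nn_conv_backward(cache$x, env$state[[paste0(prefix, ".proj.weight")]],
                           dp, cache$stride, 0L, need_dx)
    env$g <- .acc_grad(env$g, paste0(prefix, ".proj.weight"), cp$dw)
    if (need_dx) dx <- dx + cp$dx
  } else if (need_dx) {
    dx <- dx + dpre
  }
  dx
}

# dy arrives at the output of the last block in `blocks`; gradient flow
# stops below the first block (its input gradient is never materialized).
.backward_convs <- function(env, caches, blocks, dy) {
  for (bi in rev(seq_along(blocks))) {
    b <- blocks[bi]
    first <- bi == 1L
    if (b == "conv1") {
      cache <- caches[[b]]$stem
      dh <- nn_maxpool_backward(dy, cache$mp_idx, as.integer(cache$hdim))
      dh <- dh * (cache$h > 0)
      da <- .bn_bwd(env, "conv1.bn", cache, dh)
      c1 <- nn_conv_backward(cache$x_in, env$state[["conv1.conv.weight"]],
                             da, 2L, 3L, FALSE)
      env$g <- .acc_grad(env$g, "conv1.conv.weight", c1$dw)
      dy <- NULL
    } else {
      ucaches <- caches[[b]]
      for (u in rev(seq_along(ucaches))) {
        need_dx <- !(first && u == 1L)
        dy <- .unit_bwd(env, sprintf("%s.u%d", b, u), ucaches[[u]], dy, need_dx)
      }
    }
  }
  invisible(NULL)
}

.adam_init <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

# In-place fused update. Trainable tensors are deep-copied once at the
# start of training, so the state, moment and gradient buffers mutated here
# are exclusively owned by this training run.
.adam_step <- function(opt, env, keys, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (key in keys) {
    gk <- env$g[[key]]
    if (is.null(gk)) next
    if (is.null(opt$m[[key]])) {
      opt$m[[key]] <- numeric(length(gk))
      opt$v[[key]] <- numeric(length(gk))
    }
    nn_adam_inplace(env$state[[key]], gk, opt$m[[key]], opt$v[[key]],
                    cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$eps, bc1, bc2)
  }
}

.xent_grad <- function(logits, y) {
  n <- nrow(logits)
  p <- .softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], eps)))
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = d / n)
}

#' Fine-tune a partially frozen network
#'
#' Minimises softmax cross-entropy with Adam over the trainable blocks of
#' `plan`. Tensors in frozen blocks -- including batch-norm running
#' statistics, which run in inference mode there -- are returned
#' bit-identical to their input values. Deterministic given
#' `(state, plan, data, cfg)`.
#'
#' @param state a `model_state` (typically a pretrained checkpoint with a
#'   freshly replaced head).
#' @param plan a `freeze_plan`.
#' @param x standardized image array `side x side x 3 x N` (see
#'   [dataset_tensor()]), or, when `x_is_output_of` names a frozen block,
#'   that block's feature maps.
#' @param y integer class labels, 1-based.
#' @param cfg a [train_config()].
#' @param x_is_output_of optional name of a frozen conv block whose output
#'   `x` already is; lets callers reuse cached frozen features across runs.
#' @return `list(state = trained model_state, history = data.frame(epoch,
#'   loss))`.
#' @export
train <- function(state, plan, x, y, cfg = train_config(), x_is_output_of = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  if (n == 0L || length(y) == 0L) stop("empty training data")
  if (length(y) != n) stop("x and y disagree on sample count")
  nc <- attr(state, "n_classes")
  if (any(y < 1L | y > nc)) stop("labels out of range 1..", nc)

  conv_blocks <- setdiff(.block_order, "fc")
  first_trainable <- names(plan)[plan][1]
  start_block <- if (is.null(x_is_output_of)) "conv1" else {
    i <- match(x_is_output_of, conv_blocks)
    if (is.na(i)) stop("unknown block: ", x_is_output_of)
    if (any(plan[seq_len(i)]))
      stop("x_is_output_of must name a frozen-prefix block")
    if (i == length(conv_blocks)) NA_character_ else conv_blocks[i + 1L]
  }

  env <- new.env(parent = emptyenv())
  env$state <- state
  env$commit_bn <- cfg$learning_rate > 0

  # one pass through the remaining frozen prefix, inference mode
  feats <- x
  if (!is.na(start_block) && first_trainable != "fc") {
    fr_end <- match(first_trainable, conv_blocks) - 1L
    if (fr_end >= match(start_block, conv_blocks)) {
      frozen <- conv_blocks[seq(match(start_block, conv_blocks), fr_end)]
      feats <- .forward_convs(env, feats, frozen, training = FALSE)$y
    }
    trainable_convs <- conv_blocks[seq(match(first_trainable, conv_blocks),
                                       length(conv_blocks))]
  } else if (!is.na(start_block) && first_trainable == "fc") {
    frozen <- conv_blocks[seq(match(start_block, conv_blocks), length(conv_blocks))]
    feats <- .forward_convs(env, feats, frozen, training = FALSE)$y
    trainable_convs <- character(0)
  } else {
    trainable_convs <- if (first_trainable == "fc") character(0) else
      conv_blocks[seq(match(first_trainable, conv_blocks), length(conv_blocks))]
  }

  param_keys <- unlist(lapply(names(plan)[plan], .block_param_keys,
                              state = state))
  # private copies of the tensors the in-place optimiser will mutate
  for (key in param_keys) env$state[[key]] <- env$state[[key]] + 0
  opt <- .adam_init()
  history <- data.frame(epoch = integer(0), loss = numeric(0))

  for (epoch in seq_len(cfg$epochs)) {
    order <- .with_seed(cfg$seed + 131071L * epoch, sample.int(n))
    total <- 0
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[seq(b0, min(b0 + cfg$batch_size - 1L, n))]
      xb <- feats[, , , idx, drop = FALSE]
      env$g <- list()
      if (length(trainable_convs) > 0L) {
        r <- .forward_convs(env, xb, trainable_convs, training = TRUE,
                            want_cache = TRUE)
        if (trainable_convs[1] == "conv1") r$caches[["conv1"]]$stem$x_in <- xb
        top <- r$y
      } else top <- xb
      feat <- .gap(top)
      logits <- .head_fwd(env$state, feat)
      ce <- .xent_grad(logits, y[idx])
      if (!is.finite(ce$loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      total <- total + ce$loss * length(idx)
      # head gradients
      env$g <- .acc_grad(env$g, "fc.weight", t(ce$dlogits) %*% t(feat))
      env$g <- .acc_grad(env$g, "fc.bias", colSums(ce$dlogits))
      if (length(trainable_convs) > 0L) {
        d <- dim(top)
        dfeat <- t(env$state[["fc.weight"]]) %*% t(ce$dlogits)  # C x N
        dtop <- array(rep(as.vector(dfeat), each = d[1] * d[2]) / (d[1] * d[2]), d)
        .backward_convs(env, r$caches, trainable_convs, dtop)
      }
      if (cfg$learning_rate > 0) .adam_step(opt, env, param_keys, cfg)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = total / n))
  }
  list(state = env$state, history = history)
}

#' Predict class labels and probabilities
#'
#' Runs the network in inference mode. Each probability row is the softmax
#' of the logits and sums to one; the predicted label is the argmax with
#' ties broken toward the lowest class index. Predictions are independent
#' of batch order and batching.
#'
#' @param object a `model_state`.
#' @param x standardized image array `side x side x 3 x N`.
#' @param batch_size evaluation minibatch size (memory control only).
#' @param ... unused.
#' @return `list(labels = integer N (1-based class indices),
#'   probs = N x n_classes matrix)`.
#' @export
predict.model_state <- function(object, x, batch_size = 64L, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[4]
  probs <- matrix(0, n, attr(object, "n_classes"))
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- seq(b0, min(b0 + batch_size - 1L, n))
    probs[idx, ] <- .softmax(forward(object, x[, , , idx, drop = FALSE]))
  }
  list(labels = max.col(probs, ties.method = "first"), probs = probs)
}

#' Pretrain the backbone on a source-domain dataset
#'
#' Builds a fresh 34-layer network sized to the source classes and trains
#' all layers on it -- the desk-scale stand-in for large-scale natural-image
#' pretraining. The returned state is the checkpoint that transfer
#' strategies start from (after [replace_head()] for the target taxa).
#'
#' @param source_ds source-domain `fossil_dataset` (e.g. from
#'   [generate_source_domain()]).
#' @param input_side network input side used for pretraining.
#' @param cfg a [train_config()].
#' @param init_seed seed for the initial parameter draw.
#' @return `list(state = , history = )` as from [train()].
#' @export
pretrain_backbone <- function(source_ds, input_side = 224,
                              cfg = train_config(), init_seed = 0) {
  net <- build_resnet34(length(source_ds$classes), seed = init_seed,
                        input_side = input_side)
  tens <- dataset_tensor(source_ds, input_side)
  train(net$state, make_freeze_plan("TA"), tens$x, tens$y, cfg)
}
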