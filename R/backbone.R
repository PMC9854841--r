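# The 34-layer residual backbone: a 7x7/stride-2 stem with 3x3 max pooling,
# four stages of two-convolution residual units with unit plan (3, 4, 6, 3)
# and channel plan (64, 128, 256, 512), and a global-average-pool + fully
# connected head. The first unit of each of the last three stages halves the
# spatial grid and doubles the channels through a 1x1/stride-2 projection
# ("dashed-line") shortcut; every other unit adds its input unchanged
# ("solid-line" identity shortcut). Batch normalisation follows every
# convolution and is not counted among the 34 weighted layers.

.rn34_stages <- list(
  conv2_x = list(units = 3L, channels = 64L),
  conv3_x = list(units = 4L, channels = 128L),
  conv4_x = list(units = 6L, channels = 256L),
  conv5_x = list(units = 3L, channels = 512L))

.block_order <- c("conv1", "conv2_x", "conv3_x", "conv4_x", "conv5_x", "fc")

.stage_in_channels <- function(stage) {
  i <- match(stage, names(.rn34_stages))
  if (i == 1L) 64L else .rn34_stages[[i - 1L]]$channels
}

.stage_has_proj <- function(stage) .stage_in_channels(stage) != .rn34_stages[[stage]]$channels

.bn_keys <- function(prefix) {
  paste0(prefix, c(".scale", ".shift", ".running_mean", ".running_var"))
}

# Full expected key set for a given head size; the checkpoint loader
# validates against this.
.expected_keys <- function(n_classes) {
  keys <- c("conv1.conv.weight", .bn_keys("conv1.bn"))
  for (stage in names(.rn34_stages)) {
    st <- .rn34_stages[[stage]]
    for (u in seq_len(st$units)) {
      p <- sprintf("%s.u%d", stage, u)
      keys <- c(keys,
                paste0(p, ".conv1.weight"), .bn_keys(paste0(p, ".bn1")),
                paste0(p, ".conv2.weight"), .bn_keys(paste0(p, ".bn2")))
      if (u == 1L && .stage_has_proj(stage))
        keys <- c(keys, paste0(p, ".proj.weight"), .bn_keys(paste0(p, ".projbn")))
    }
  }
  c(keys, "fc.weight", "fc.bias")
}

.he_conv <- function(kh, kw, cin, cout) {
  # He initialisation, fan-out mode: sd = sqrt(2 / (k*k*cout))
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cout))),
        c(kh, kw, cin, cout))
}

.init_bn <- function(state, prefix, c) {
  state[[paste0(prefix, ".scale")]] <- rep(1, c)
  state[[paste0(prefix, ".shift")]] <- rep(0, c)
  state[[paste0(prefix, ".running_mean")]] <- rep(0, c)
  state[[paste0(prefix, ".running_var")]] <- rep(1, c)
  state
}

.init_fc <- function(n_classes) {
  b <- 1 / sqrt(512)
  list(weight = matrix(runif(n_classes * 512, -b, b), n_classes, 512),
       bias = runif(n_classes, -b, b))
}

#' Build the 34-layer residual network
#'
#' Constructs the architecture description and a freshly initialised
#' parameter set. Convolutions use seeded He (fan-out) initialisation,
#' batch-norm scales start at one and shifts at zero, and the fully
#' connected head uses a small uniform draw.
#'
#' @param n_classes number of output classes, `>= 2`.
#' @param seed integer seed for the initial draw.
#' @param input_side expected input image side in pixels (default 224, the
#'   pretrained-weights convention); any multiple of 32 from 32 up works
#'   because the head is size-agnostic through global average pooling.
#' @return `list(spec = , state = )`: a `backbone_spec` and a `model_state`
#'   (named list of parameter tensors).
#' @export
build_resnet34 <- function(n_classes, seed = 0, input_side = 224) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (input_side < 32 || input_side %% 32 != 0)
    stop("input_side must be a positive multiple of 32")
  state <- .with_seed(seed, {
    st <- list()
    st[["conv1.conv.weight"]] <- .he_conv(7L, 7L, 3L, 64L)
    st <- .init_bn(st, "conv1.bn", 64L)
    for (stage in names(.rn34_stages)) {
      plan <- .rn34_stages[[stage]]
      cin <- .stage_in_channels(stage)
      cout <- plan$channels
      for (u in seq_len(plan$units)) {
        p <- sprintf("%s.u%d", stage, u)
        ci <- if (u == 1L) cin else cout
        st[[paste0(p, ".conv1.weight")]] <- .he_conv(3L, 3L, ci, cout)
        st <- .init_bn(st, paste0(p, ".bn1"), cout)
        st[[paste0(p, ".conv2.weight")]] <- .he_conv(3L, 3L, cout, cout)
        st <- .init_bn(st, paste0(p, ".bn2"), cout)
        if (u == 1L && .stage_has_proj(stage)) {
          st[[paste0(p, ".proj.weight")]] <- .he_conv(1L, 1L, cin, cout)
          st <- .init_bn(st, paste0(p, ".projbn"), cout)
        }
      }
    }
    fc <- .init_fc(n_classes)
    st[["fc.weight"]] <- fc$weight
    st[["fc.bias"]] <- fc$bias
    st
  })
  attr(state, "n_classes") <- as.integer(n_classes)
  attr(state, "input_side") <- as.integer(input_side)
  class(state) <- "model_state"
  list(spec = backbone_spec(n_classes, input_side), state = state)
}

#' Architecture description of the 34-layer backbone
#'
#' @param n_classes head output dimension.
#' @param input_side expected input side in pixels.
#' @return object of class `backbone_spec` with the stage plan (units,
#'   channels and shortcut type per stage) and head description.
#' @export
backbone_spec <- function(n_classes, input_side = 224) {
  stage_plan <- c(
    list(conv1 = list(kind = "stem", conv = "7x7/2", pool = "3x3 max/2",
                      channels = 64L)),
    lapply(names(.rn34_stages), function(s) {
      list(kind = "residual", units = .rn34_stages[[s]]$units,
           channels = .rn34_stages[[s]]$channels,
           first_shortcut = if (.stage_has_proj(s)) "projection" else "identity")
    }))
  names(stage_plan) <- c("conv1", names(.rn34_stages))
  structure(list(stage_plan = stage_plan,
                 head = "global average pool + fully connected",
                 n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side)),
            class = "backbone_spec")
}

#' Count the weighted layers on the inference path
#'
#' The stem convolution, two convolutions per residual unit, and the fully
#' connected layer: `1 + 2*(3+4+6+3) + 1 = 34`. Projection shortcuts and
#' batch-norm layers are not counted, following the usual convention for
#' this architecture's depth naming.
#'
#' @param spec a `backbone_spec`.
#' @return integer layer count.
#' @export
count_weighted_layers <- function(spec) {
  res <- spec$stage_plan[vapply(spec$stage_plan, function(s) s$kind == "residual",
                                logical(1))]
  1L + sum(vapply(res, function(s) 2L * s$units, integer(1))) + 1L
}

#' Number of projection (dashed-line) shortcuts in the architecture
#' @param spec a `backbone_spec`.
#' @export
count_projection_shortcuts <- function(spec) {
  sum(vapply(spec$stage_plan, function(s)
    identical(s$first_shortcut, "projection"), logical(1)))
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> ResNet-34, %d classes, input %dx%d\n",
              x$n_classes, x$input_side, x$input_side))
  for (nm in names(x$stage_plan)) {
    s <- x$stage_plan[[nm]]
    if (s$kind == "stem")
      cat(sprintf("  %-8s %s conv + %s pool, %d ch\n", nm, s$conv, s$pool, s$channels))
    else
      cat(sprintf("  %-8s %d units x %d ch, first shortcut: %s\n",
                  nm, s$units, s$channels, s$first_shortcut))
  }
  cat("  head    ", x$head, "\n")
  invisible(x)
}

#' @export
print.model_state <- function(x, ...) {
  np <- sum(vapply(x, length, numeric(1)))
  cat(sprintf("<model_state> %d tensors, %.2fM values, %d classes\n",
              length(x), np / 1e6, attr(x, "n_classes")))
  invisible(x)
}

.relu <- function(x) { x[x < 0] <- 0; x }

# Conv -> BN. In training mode BN uses batch statistics and (optionally)
# commits updated running statistics into `env$state`; in inference mode it
# consumes the stored running statistics.
.conv_bn <- function(env, wkey, bnp, x, stride, pad, training, cache = NULL) {
  a <- nn_conv_forward(x, env$state[[wkey]], stride, pad)
  bn <- nn_bn_forward(a, env$state[[paste0(bnp, ".scale")]],
                      env$state[[paste0(bnp, ".shift")]],
                      env$state[[paste0(bnp, ".running_mean")]],
                      env$state[[paste0(bnp, ".running_var")]],
                      training, 0.1, 1e-5)
  if (training && isTRUE(env$commit_bn)) {
    env$state[[paste0(bnp, ".running_mean")]] <- bn$running_mean
    env$state[[paste0(bnp, ".running_var")]] <- bn$running_var
  }
  if (!is.null(cache)) {
    cache[[paste0(bnp, ".in")]] <- a
    cache[[paste0(bnp, ".mean")]] <- bn$mean
    cache[[paste0(bnp, ".invstd")]] <- bn$invstd
  }
  bn$y
}

# One residual unit. Returns the activation and, when caching for backward,
# the intermediate tensors keyed for .unit_backward.
.unit_fwd <- function(env, prefix, x, stride, has_proj, training, want_cache) {
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  h <- .conv_bn(env, paste0(prefix, ".conv1.weight"), paste0(prefix, ".bn1"),
                x, stride, 1L, training, cache)
  h <- .relu(h)
  f <- .conv_bn(env, paste0(prefix, ".conv2.weight"), paste0(prefix, ".bn2"),
                h, 1L, 1L, training, cache)
  s <- if (has_proj) {
    .conv_bn(env, paste0(prefix, ".proj.weight"), paste0(prefix, ".projbn"),
             x, stride, 0L, training, cache)
  } else x
  y <- .relu(f + s)
  if (want_cache) {
    cache$x <- x; cache$h <- h; cache$y <- y
    cache$stride <- stride; cache$has_proj <- has_proj
  }
  list(y = y, cache = cache)
}

# Blocks between `from` and `to` (inclusive, conv blocks only), e.g. the
# frozen prefix or the trainable suffix of the feature extractor.
.conv_blocks_between <- function(from, to) {
  blocks <- setdiff(.block_order, "fc")
  blocks[seq(match(from, blocks), match(to, blocks))]
}

# Forward through a contiguous run of conv blocks. Returns the output map
# and (when want_cache) the per-unit caches needed for the backward pass.
.forward_convs <- function(env, x, blocks, training = FALSE, want_cache = FALSE) {
  caches <- if (want_cache) list()
  for (b in blocks) {
    if (b == "conv1") {
      cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
      a <- .conv_bn(env, "conv1.conv.weight", "conv1.bn", x, 2L, 3L, training, cache)
      h <- .relu(a)
      mp <- nn_maxpool_forward(h, 3L, 2L, 1L)
      x <- mp$y
      if (want_cache) {
        cache$x_in <- NULL  # stem input gradient never needed
        cache$h <- h; cache$mp_idx <- mp$idx; cache$hdim <- dim(h)
        caches[[b]] <- list(stem = cache)
      }
    } else {
      st <- .rn34_stages[[b]]
      ucaches <- if (want_cache) vector("list", st$units)
      for (u in seq_len(st$units)) {
        stride <- if (u == 1L && .stage_has_proj(b)) 2L else 1L
        has_proj <- u == 1L && .stage_has_proj(b)
        r <- .unit_fwd(env, sprintf("%s.u%d", b, u), x, stride, has_proj,
                       training, want_cache)
        x <- r$y
        if (want_cache) ucaches[[u]] <- r$cache
      }
      if (want_cache) caches[[b]] <- ucaches
    }
  }
  list(y = x, caches = caches)
}

# Global average pool (H,W,C,N) -> (C,N), then the linear head -> N x K.
.gap <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

.head_fwd <- function(state, feat) {
  t(state[["fc.weight"]] %*% feat + state[["fc.bias"]])
}

.softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

#' Forward pass: standardized image batch to class logits
#'
#' Runs the full backbone in inference mode (batch-norm running statistics,
#' no parameter updates). Inputs must be standardized images at the side
#' the model was built for.
#'
#' @param state a `model_state`.
#' @param x numeric array `side x side x 3 x N` of standardized images
#'   (a single `side x side x 3` image is also accepted).
#' @return `N x n_classes` matrix of logits.
#' @export
forward <- function(state, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  side <- attr(state, "input_side")
  if (dim(x)[1] != side || dim(x)[2] != side)
    stop("wrong spatial size: expected ", side, "x", side,
         ", got ", dim(x)[1], "x", dim(x)[2])
  env <- new.env(parent = emptyenv())
  env$state <- state
  r <- .forward_convs(env, x, setdiff(.block_order, "fc"), training = FALSE)
  .head_fwd(state, .gap(r$y))
}

#' Forward one residual unit
#'
#' Applies a single residual unit to a feature map: `relu(x + F(x))` for a
#' solid-line (identity) unit, or `relu(P(x) + F(x))` for a dashed-line
#' unit, where the projection `P` is a 1x1/stride-2 convolution + batch
#' norm that halves the grid and changes the channel count.
#'
#' @param unit_state named list of the unit's tensors with keys
#'   `conv1.weight`, `bn1.*`, `conv2.weight`, `bn2.*` and, for a projection
#'   unit, `proj.weight`, `projbn.*` (see [unit_state()]).
#' @param x input feature map `H x W x C x N`.
#' @return output feature map.
#' @export
residual_unit_forward <- function(unit_state, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cin <- dim(unit_state[["conv1.weight"]])[3]
  if (dim(x)[3] != cin)
    stop("channel mismatch: unit expects ", cin, " channels, got ", dim(x)[3])
  has_proj <- "proj.weight" %in% names(unit_state)
  env <- new.env(parent = emptyenv())
  env$state <- stats::setNames(unit_state, paste0("u.", names(unit_state)))
  .unit_fwd(env, "u", x, if (has_proj) 2L else 1L, has_proj,
            training = FALSE, want_cache = FALSE)$y
}

#' Extract one residual unit's tensors from a model state
#'
#' @param state a `model_state`.
#' @param stage stage name, one of `"conv2_x"`, `"conv3_x"`, `"conv4_x"`,
#'   `"conv5_x"`.
#' @param unit unit index within the stage (1-based).
#' @return named list of the unit's tensors, suitable for
#'   [residual_unit_forward()].
#' @export
unit_state <- function(state, stage, unit) {
  stage <- match.arg(stage, names(.rn34_stages))
  stopifnot(unit >= 1, unit <= .rn34_stages[[stage]]$units)
  p <- sprintf("%s.u%d.", stage, unit)
  keys <- names(state)[startsWith(names(state), p)]
  stats::setNames(state[keys], substring(keys, nchar(p) + 1L))
}

#' Replace the classifier head
#'
#' Re-initialises the fully connected layer for a new number of target
#' classes; every other tensor is carried over bit-exactly. This is the
#' step that adapts a source-pretrained checkpoint to the target taxa.
#'
#' @param state a `model_state`.
#' @param n_classes new head size.
#' @param seed seed for the fresh head draw.
#' @return a `model_state` with `fc.weight` of shape `n_classes x 512`.
#' @export
replace_head <- function(state, n_classes, seed = 0) {
  .fresh_head(state, n_classes, seed)
}

.fresh_head <- function(state, n_classes, seed) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  fc <- .with_seed(seed, .init_fc(n_classes))
  state[["fc.weight"]] <- fc$weight
  state[["fc.bias"]] <- fc$bias
  attr(state, "n_classes") <- as.integer(n_classes)
  state
}

.CKPT_MAGIC <- "FNCKPT01"

#' Save a model state as a single-file named-tensor checkpoint
#'
#' A simple portable container: magic string, head size, input side, then
#' each tensor as (key, dims, little-endian doubles). Round-trips every
#' tensor bit-exactly.
#'
#' @param state a `model_state`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.CKPT_MAGIC), con)
  writeBin(c(attr(state, "n_classes"), attr(state, "input_side"),
             length(state)), con, size = 4L, endian = "little")
  for (key in names(state)) {
    nm <- charToRaw(key)
    tensor <- state[[key]]
    d <- dim(tensor)
    if (is.null(d)) d <- length(tensor)
    writeBin(c(length(nm), length(d)), con, size = 4L, endian = "little")
    writeBin(nm, con)
    writeBin(as.integer(d), con, size = 4L, endian = "little")
    writeBin(as.numeric(tensor), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Load a model-state checkpoint
#'
#' Validates the stored key set against the expected backbone structure.
#' When the stored head size differs from `expect_classes`, the load fails
#' unless `replace_head = TRUE`, in which case the body tensors come from
#' the file and a fresh seeded head of the requested size is attached.
#'
#' @param path checkpoint file.
#' @param expect_classes required head size (optional).
#' @param replace_head tolerate a head-size mismatch by re-initialising the
#'   fully connected layer.
#' @param seed seed for the fresh head when one is created.
#' @return a `model_state`.
#' @export
load_checkpoint <- function(path, expect_classes = NULL, replace_head = FALSE,
                            seed = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(rawToChar(readBin(con, "raw", nchar(.CKPT_MAGIC))),
                    error = function(e) "")
  if (!identical(magic, .CKPT_MAGIC))
    stop("not a fossilnet checkpoint: ", path)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (length(hdr) != 3L || any(hdr <= 0L))
    stop("corrupt checkpoint header in ", path)
  n_classes <- hdr[1]; input_side <- hdr[2]; n_tensors <- hdr[3]
  state <- vector("list", n_tensors)
  keys <- character(n_tensors)
  for (i in seq_len(n_tensors)) {
    sz <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    if (length(sz) != 2L) stop("corrupt checkpoint: truncated at tensor ", i)
    keys[i] <- rawToChar(readBin(con, "raw", sz[1]))
    d <- readBin(con, "integer", sz[2], size = 4L, endian = "little")
    vals <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
    if (length(vals) != prod(d))
      stop("corrupt checkpoint: truncated tensor '", keys[i], "'")
    state[[i]] <- if (length(d) > 1L) array(vals, d) else vals
  }
  names(state) <- keys
  expected <- .expected_keys(n_classes)
  missing <- setdiff(expected, keys)
  if (length(missing) > 0L)
    stop("checkpoint missing keys: ", paste(missing, collapse = ", "))
  extra <- setdiff(keys, expected)
  if (length(extra) > 0L)
    stop("checkpoint has unexpected keys: ", paste(extra, collapse = ", "))
  state <- state[expected]  # canonical order; loading is order-independent
  attr(state, "n_classes") <- n_classes
  attr(state, "input_side") <- input_side
  class(state) <- "model_state"
  if (!is.null(expect_classes) && expect_classes != n_classes) {
    if (!replace_head)
      stop("checkpoint head has ", n_classes, " classes but ", expect_classes,
           " expected; pass replace_head = TRUE to re-initialise the head")
    state <- .fresh_head(state, expect_classes, seed)
  }
  state
}
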