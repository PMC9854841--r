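# Machine-learning comparator: histogram-of-oriented-gradients features
# with a support-vector classifier, plugged into the same splits and
# metrics as the network models.

#' HOG descriptor configuration
#'
#' @param cell_size cell side in pixels; `image_side` must be divisible by it.
#' @param block_size block side in cells (default 2, i.e. 2x2 cells).
#' @param block_stride block stride in cells (default 1, overlapping blocks).
#' @param n_bins orientation bins over the unsigned 0--180 degree range.
#' @param image_side side the image is resized to before extraction.
#' @return object of class `hog_config`.
#' @export
hog_config <- function(cell_size = 8, block_size = 2, block_stride = 1,
                       n_bins = 9, image_side = 224) {
  stopifnot(block_size >= 1, n_bins >= 2, block_stride >= 1)
  if (image_side %% cell_size != 0)
    stop("image_side (", image_side, ") not divisible by cell_size (",
         cell_size, ")")
  structure(list(cell_size = as.integer(cell_size),
                 block_size = as.integer(block_size),
                 block_stride = as.integer(block_stride),
                 n_bins = as.integer(n_bins),
                 image_side = as.integer(image_side)),
            class = "hog_config")
}

#' Expected HOG descriptor length for a configuration
#'
#' `n_blocks_x * n_blocks_y * block_size^2 * n_bins`, with
#' `n_blocks = (cells_per_side - block_size) / block_stride + 1` sliding
#' blocks per axis.
#'
#' @param cfg a [hog_config()].
#' @return integer descriptor length.
#' @export
hog_length <- function(cfg) {
  cells <- cfg$image_side %/% cfg$cell_size
  nb <- (cells - cfg$block_size) %/% cfg$block_stride + 1L
  nb * nb * cfg$block_size^2 * cfg$n_bins
}

.luminance <- function(px) {
  if (is.matrix(px)) return(px)
  px <- .as_pixels(px)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Histogram-of-oriented-gradients feature vector
#'
#' Computes unsigned-orientation HOG: central-difference gradients on the
#' edge-replicated grayscale image, magnitude-weighted hard assignment of
#' each pixel to one of `n_bins` orientation bins over 0--180 degrees,
#' per-cell histograms, and L2-normalised sliding-block descriptors
#' (an all-zero block stays zero). Colour inputs are converted to
#' luminance grayscale first.
#'
#' @param img grayscale matrix, `image_sample` or `H x W x 3` array,
#'   already at `cfg$image_side` (use [resize_image()] upstream).
#' @param cfg a [hog_config()].
#' @return numeric vector of length [hog_length()]; blocks are concatenated
#'   row-major, cells within a block row-major, bins innermost.
#' @export
hog_features <- function(img, cfg = hog_config()) {
  g <- .luminance(img)
  side <- cfg$image_side
  if (nrow(g) != side || ncol(g) != side)
    stop("image must be ", side, "x", side, ", got ", nrow(g), "x", ncol(g))
  # central differences on the edge-replicated image
  gp <- rbind(g[1, ], g, g[side, ])
  gp <- cbind(gp[, 1], gp, gp[, side])
  gx <- (gp[2:(side + 1), 3:(side + 2)] - gp[2:(side + 1), 1:side]) / 2
  gy <- (gp[3:(side + 2), 2:(side + 1)] - gp[1:side, 2:(side + 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) * 180 / pi
  theta <- theta %% 180  # unsigned orientation in [0, 180)
  bin <- pmin(floor(theta / (180 / cfg$n_bins)) + 1L, cfg$n_bins)

  cells <- side %/% cfg$cell_size
  # per-cell orientation histograms: cells x cells x n_bins
  cr <- (row(g) - 1L) %/% cfg$cell_size + 1L
  cc <- (col(g) - 1L) %/% cfg$cell_size + 1L
  idx <- cr + (cc - 1L) * cells + (bin - 1L) * cells * cells
  hist <- array(0, c(cells, cells, cfg$n_bins))
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  hist[as.integer(names(acc))] <- acc

  nb <- (cells - cfg$block_size) %/% cfg$block_stride + 1L
  out <- numeric(nb * nb * cfg$block_size^2 * cfg$n_bins)
  k <- 0L
  blen <- cfg$block_size^2 * cfg$n_bins
  for (br in seq_len(nb)) {
    for (bc in seq_len(nb)) {
      r0 <- (br - 1L) * cfg$block_stride
      c0 <- (bc - 1L) * cfg$block_stride
      v <- numeric(blen)
      j <- 0L
      for (dr in seq_len(cfg$block_size)) {
        for (dc in seq_len(cfg$block_size)) {
          v[j + seq_len(cfg$n_bins)] <- hist[r0 + dr, c0 + dc, ]
          j <- j + cfg$n_bins
        }
      }
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out[k + seq_len(blen)] <- v
      k <- k + blen
    }
  }
  out
}

# HOG feature matrix (rows = samples) for a whole dataset.
.hog_matrix <- function(ds, cfg) {
  t(vapply(ds$samples, function(s)
    hog_features(resize_image(s$pixels, cfg$image_side), cfg),
    numeric(hog_length(cfg))))
}

#' Train the SVM baseline on feature vectors
#'
#' Fits a one-vs-one soft-margin support-vector classifier with a
#' radial-basis kernel (via \pkg{e1071}). Runs even with a single sample
#' per class, where its test performance is expected to collapse -- the
#' regime in which feature-engineered machine learning breaks down and
#' transfer-learned networks keep working.
#'
#' @param features numeric matrix, rows = samples.
#' @param labels integer class indices (1-based) or factor; at least two
#'   distinct classes.
#' @param params list: `cost` (default 10), `gamma` (default
#'   `1/ncol(features)`), `seed`.
#' @return object of class `svm_baseline` with a [predict()] method
#'   returning integer class indices.
#' @export
train_svm_baseline <- function(features, labels, params = list()) {
  if (length(unique(labels)) < 2L)
    stop("need at least two classes to train the SVM baseline")
  cost <- if (is.null(params$cost)) 10 else params$cost
  gamma <- if (is.null(params$gamma)) 1 / ncol(features) else params$gamma
  seed <- if (is.null(params$seed)) 0 else params$seed
  y <- factor(as.integer(labels))
  fit <- .with_seed(seed,
    e1071::svm(x = features, y = y, kernel = "radial", cost = cost,
               gamma = gamma, scale = FALSE))
  structure(list(fit = fit, levels = levels(y)), class = "svm_baseline")
}

#' @param object an `svm_baseline`.
#' @param newdata feature matrix to classify.
#' @param ... unused.
#' @rdname train_svm_baseline
#' @export
predict.svm_baseline <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$fit, newdata)))
}
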