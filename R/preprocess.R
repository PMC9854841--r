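# Preprocessing pipeline: chroma-key background removal, affine
# augmentation, Gaussian noise, centre-crop resizing and per-image
# standardization. All operations accept either an image_sample or a plain
# H x W x 3 pixel array and return the same kind of object they were given.

.as_pixels <- function(img) if (inherits(img, "image_sample")) img$pixels else img

.rewrap <- function(img, pixels) {
  if (inherits(img, "image_sample")) { img$pixels <- pixels; img } else pixels
}

#' Chroma-key specification for background removal
#'
#' A pixel counts as background when its hue lies within `hue_tol` of the
#' reference background hue (circularly, hue on `[0, 1)`) and both its
#' saturation and value exceed the given floors; dark or grey fossil pixels
#' therefore never match even when their hue is bluish.
#'
#' @param rgb reference background colour, length-3 in 0--255. The default
#'   matches the uniform blue imaging background of the synthetic generator.
#' @param hue_tol circular hue tolerance in `[0, 0.5]`.
#' @param sat_min,val_min minimum saturation / value (0--1 scale) for a
#'   pixel to be eligible as background.
#' @param fill replacement colour for matched pixels (default black).
#' @return object of class `chroma_key`.
#' @export
chroma_key <- function(rgb = c(40, 90, 200), hue_tol = 0.10,
                       sat_min = 0.30, val_min = 0.20, fill = c(0, 0, 0)) {
  stopifnot(length(rgb) == 3, hue_tol >= 0, hue_tol <= 0.5, length(fill) == 3)
  hsv <- grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  structure(list(rgb = rgb, hue = hsv[1, 1], hue_tol = hue_tol,
                 sat_min = sat_min, val_min = val_min, fill = fill),
            class = "chroma_key")
}

#' Remove the uniform imaging background from an image
#'
#' Replaces every pixel matching the chroma key by the fill colour, leaving
#' foreground (fossil) pixels untouched. A no-op when nothing matches.
#'
#' @param img `image_sample` or `H x W x 3` array (0--255).
#' @param bg a [chroma_key()] policy.
#' @return same type as `img`, with background pixels set to `bg$fill`.
#' @export
remove_background <- function(img, bg = chroma_key()) {
  px <- .as_pixels(img)
  d <- dim(px)
  m <- matrix(px, d[1] * d[2], 3L)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  dh <- abs(hsv[1, ] - bg$hue)
  dh <- pmin(dh, 1 - dh)  # circular hue distance
  mask <- dh <= bg$hue_tol & hsv[2, ] >= bg$sat_min & hsv[3, ] >= bg$val_min
  m[mask, ] <- rep(bg$fill, each = sum(mask))
  .rewrap(img, array(m, d))
}

# Inverse-mapped affine resampling on the pixel grid. A is the 2x2 forward
# matrix acting on centred (col, row) coordinates; shift is a forward
# translation in pixels. Out-of-frame sources read as `fill`.
.affine_sample <- function(px, A, shift = c(0, 0),
                           interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- dim(px)
  H <- d[1]; W <- d[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  u <- rep(seq_len(W), each = H) - cx - shift[1]   # centred output cols
  v <- rep(seq_len(H), times = W) - cy - shift[2]  # centred output rows
  Ai <- solve(A)
  sx <- Ai[1, 1] * u + Ai[1, 2] * v + cx  # source col
  sy <- Ai[2, 1] * u + Ai[2, 2] * v + cy  # source row
  out <- array(fill, d)
  if (interp == "nearest") {
    rc <- round(sy); cc <- round(sx)
    ok <- rc >= 1 & rc <= H & cc >= 1 & cc <= W
    for (ch in 1:3) {
      o <- matrix(fill[min(ch, length(fill))], H, W)
      o[ok] <- px[cbind(rc[ok], cc[ok], ch)]
      out[, , ch] <- o
    }
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    # exact grid hits on the border are still valid
    edge <- sy >= 1 & sy <= H & sx >= 1 & sx <= W & !ok
    for (ch in 1:3) {
      o <- matrix(fill[min(ch, length(fill))], H, W)
      if (any(ok)) {
        o[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * px[cbind(r0[ok], c0[ok], ch)] +
                 (1 - fr[ok]) * fc[ok]       * px[cbind(r0[ok], c0[ok] + 1, ch)] +
                 fr[ok]       * (1 - fc[ok]) * px[cbind(r0[ok] + 1, c0[ok], ch)] +
                 fr[ok]       * fc[ok]       * px[cbind(r0[ok] + 1, c0[ok] + 1, ch)]
      }
      if (any(edge)) {
        rcl <- pmin(pmax(round(sy[edge]), 1), H)
        ccl <- pmin(pmax(round(sx[edge]), 1), W)
        o[edge] <- px[cbind(rcl, ccl, ch)]
      }
      out[, , ch] <- o
    }
  }
  out
}

#' Apply one affine augmentation transform
#'
#' Translation, rotation, shearing or scaling about the image centre. The
#' canvas (pixel dimensions) is preserved; content moved out of frame is
#' lost and exposed regions take the fill value. Rotation through a
#' multiple of 360 degrees, unit scaling, zero shear and zero translation
#' are bit-exact identities.
#'
#' @param img `image_sample` or pixel array.
#' @param kind one of `"translate"`, `"rotate"`, `"shear"`, `"scale"`.
#' @param magnitude for translate, `c(dx, dy)` in pixels (a scalar is used
#'   for both axes); for rotate/shear, degrees; for scale, a positive factor.
#' @param interp `"bilinear"` (default) or `"nearest"` (exact pixel
#'   permutations for right-angle rotations).
#' @param fill fill intensity for exposed regions (default 0, matching the
#'   background-removal fill).
#' @return same type as `img`.
#' @export
affine_transform <- function(img, kind = c("translate", "rotate", "shear", "scale"),
                             magnitude, interp = c("bilinear", "nearest"),
                             fill = 0) {
  kind <- match.arg(kind)
  interp <- match.arg(interp)
  if (!all(is.finite(magnitude)))
    stop("magnitude must be finite, got ", paste(magnitude, collapse = ", "))
  px <- .as_pixels(img)
  A <- diag(2)
  shift <- c(0, 0)
  if (kind == "translate") {
    shift <- if (length(magnitude) == 1L) c(magnitude, magnitude) else magnitude[1:2]
    if (all(shift == 0)) return(img)
  } else if (kind == "rotate") {
    if (magnitude %% 360 == 0) return(img)
    th <- magnitude * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else if (kind == "shear") {
    if (magnitude == 0) return(img)
    A <- matrix(c(1, 0, tan(magnitude * pi / 180), 1), 2, 2)
  } else {
    if (magnitude <= 0) stop("scale factor must be positive")
    if (magnitude == 1) return(img)
    A <- diag(2) * magnitude
  }
  .rewrap(img, .affine_sample(px, A, shift, interp, fill))
}

#' Add seeded Gaussian pixel noise
#'
#' `clip(round(x + N(0, sigma^2)), 0, 255)` per pixel and channel;
#' identical output for identical seeds, identity for `sigma = 0`.
#'
#' @param img `image_sample` or pixel array.
#' @param sigma noise standard deviation on the 0--255 intensity scale.
#' @param seed integer seed.
#' @return same type as `img`.
#' @export
add_gaussian_noise <- function(img, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(img)
  px <- .as_pixels(img)
  noisy <- .with_seed(seed, px + rnorm(length(px), sd = sigma))
  .rewrap(img, pmin(pmax(round(noisy), 0), 255))
}

#' Standardize an image to zero mean and unit variance per channel
#'
#' Implements the per-image normalization `(X - X_mean) / X_std` with the
#' mean and population standard deviation taken per channel over the whole
#' image. A channel whose standard deviation falls below `1e-8` is emitted
#' as all zeros and flagged degenerate rather than divided through.
#'
#' @param img `image_sample` or pixel array (any numeric scale).
#' @return object of class `standardized_image`: list with `values`
#'   (`H x W x 3` numeric), `mean_used`, `std_used` (per channel) and
#'   `degenerate` (logical per channel).
#' @export
standardize <- function(img) {
  px <- .as_pixels(img)
  d <- dim(px)
  m <- matrix(px, prod(d[1:2]), d[3])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)  # population sd
  degen <- sdv < 1e-8
  vals <- sweep(m, 2L, mu, "-")
  vals[, !degen] <- sweep(vals[, !degen, drop = FALSE], 2L, sdv[!degen], "/")
  vals[, degen] <- 0
  structure(list(values = array(vals, d), mean_used = mu, std_used = sdv,
                 degenerate = degen),
            class = "standardized_image")
}

#' Centre-crop to a square and resize
#'
#' Crops the central square (shorter side) and bilinearly resizes to
#' `side x side`, the input geometry expected by the network backbone.
#' An image already at the target size is returned unchanged.
#'
#' @param img `image_sample` or pixel array.
#' @param side target side in pixels, `>= 32` (default 224).
#' @param interp `"bilinear"` or `"nearest"`.
#' @return same type as `img`, `side x side x 3`.
#' @export
resize_image <- function(img, side = 224, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(side >= 32)
  px <- .as_pixels(img)
  d <- dim(px)
  s <- min(d[1], d[2])
  r0 <- floor((d[1] - s) / 2)
  c0 <- floor((d[2] - s) / 2)
  px <- px[r0 + seq_len(s), c0 + seq_len(s), , drop = FALSE]
  if (s != side) {
    eb <- EBImage::Image(aperm(px / 255, c(2L, 1L, 3L)), colormode = "Color")
    eb <- EBImage::resize(eb, w = side, h = side,
                          filter = if (interp == "bilinear") "bilinear" else "none")
    px <- pmin(pmax(round(aperm(EBImage::imageData(eb), c(2L, 1L, 3L)) * 255), 0), 255)
  }
  .rewrap(img, px)
}

#' Augmentation configuration
#'
#' Bounds and switches for the stochastic training-set augmentation:
#' translation, rotation, shearing, scaling and Gaussian noise. Magnitudes
#' are drawn uniformly within the bounds for each generated copy.
#'
#' @param translate,rotate,shear,scale,gaussian_noise logical switches.
#' @param translate_max_frac maximum |translation| as a fraction of each
#'   image side (default 0.10).
#' @param rotate_max_deg maximum |rotation| in degrees (default 30).
#' @param shear_max_deg maximum |shear| in degrees (default 10).
#' @param scale_range multiplicative scaling range (default `c(0.8, 1.25)`).
#' @param noise_sigma Gaussian noise sd on the 0--255 scale (default 8).
#' @param copies_per_image augmented copies generated per original
#'   (default 5).
#' @param seed integer seed governing all randomness of one augmentation run.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(translate = TRUE, rotate = TRUE, shear = TRUE,
                                scale = TRUE, gaussian_noise = TRUE,
                                translate_max_frac = 0.10, rotate_max_deg = 30,
                                shear_max_deg = 10, scale_range = c(0.8, 1.25),
                                noise_sigma = 8, copies_per_image = 5,
                                seed = 0) {
  stopifnot(scale_range[1] > 0, noise_sigma >= 0, copies_per_image >= 1)
  structure(list(translate = translate, rotate = rotate, shear = shear,
                 scale = scale, gaussian_noise = gaussian_noise,
                 translate_max_frac = translate_max_frac,
                 rotate_max_deg = rotate_max_deg, shear_max_deg = shear_max_deg,
                 scale_range = scale_range, noise_sigma = noise_sigma,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# One stochastic augmented copy of a pixel array, all draws from the
# current RNG stream (caller seeds it).
.augment_once <- function(px, cfg) {
  d <- dim(px)
  if (cfg$translate) {
    dx <- runif(1, -1, 1) * cfg$translate_max_frac * d[2]
    dy <- runif(1, -1, 1) * cfg$translate_max_frac * d[1]
    px <- affine_transform(px, "translate", c(dx, dy))
  }
  if (cfg$rotate)
    px <- affine_transform(px, "rotate", runif(1, -1, 1) * cfg$rotate_max_deg)
  if (cfg$shear)
    px <- affine_transform(px, "shear", runif(1, -1, 1) * cfg$shear_max_deg)
  if (cfg$scale)
    px <- affine_transform(px, "scale", runif(1, cfg$scale_range[1], cfg$scale_range[2]))
  if (cfg$gaussian_noise && cfg$noise_sigma > 0)
    px <- pmin(pmax(round(px + rnorm(length(px), sd = cfg$noise_sigma)), 0), 255)
  px
}

#' Augment every sample of a training dataset
#'
#' Each input sample is kept and additionally yields `copies_per_image`
#' stochastic augmented copies with inherited labels, so per-class balance
#' is preserved exactly. Deterministic given `cfg$seed`. Intended for
#' training data only; held-out test images should stay raw.
#'
#' @param ds a `fossil_dataset`.
#' @param cfg an [augmentation_config()].
#' @return a `fossil_dataset` with `(copies_per_image + 1) * length(ds)`
#'   samples.
#' @export
augment_dataset <- function(ds, cfg = augmentation_config()) {
  out <- vector("list", length(ds$samples) * (cfg$copies_per_image + 1L))
  k <- 0L
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    out[[k <- k + 1L]] <- s
    for (j in seq_len(cfg$copies_per_image)) {
      px <- .with_seed(cfg$seed + 131L * i + j, .augment_once(s$pixels, cfg))
      a <- s
      a$pixels <- px
      a$source_path <- paste0(s$source_path, "#aug", j)
      out[[k <- k + 1L]] <- a
    }
  }
  fossil_dataset(out, classes = ds$classes)
}
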