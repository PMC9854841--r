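# Procedural synthetic microfossil imagery. Nine shape families mirror the
# visual character of the target taxa (cone-shaped tubes, spheres, towers,
# curved spines, shells, slotted tubes, worms, segmented tubes and an
# irregular-dross catch-all), rendered as greyscale fossils on the uniform
# blue imaging background. A separate multi-class "source domain" of
# composite geometric/texture classes -- disjoint from the nine families by
# construction but sharing low-level statistics (edges, curvature, greyscale
# texture, the same background) -- supports desk-scale pretraining in place
# of large natural-image collections.

.taxon_families <- c("cone_tube", "sphere", "cone_tower", "curved_spine",
                     "shell", "slotted_tube", "worm", "segmented_tube",
                     "irregular_dross")

.BG_RGB <- c(40, 90, 200)

.texture_bands <- list(white = c(190, 240), gray = c(110, 170),
                       black = c(35, 85))

#' Specification of one synthetic taxon
#'
#' @param family one of `"cone_tube"`, `"sphere"`, `"cone_tower"`,
#'   `"curved_spine"`, `"shell"`, `"slotted_tube"`, `"worm"`,
#'   `"segmented_tube"`, `"irregular_dross"`.
#' @param size_mean nominal fossil size as a fraction of the frame,
#'   in (0, 1).
#' @param size_jitter relative size variability (fraction of `size_mean`).
#' @param shape_jitter dimensionless variability of position and
#'   family-internal shape parameters; 0 renders the canonical centred form.
#' @param fragmentation_prob probability that the rendered fossil is
#'   clipped to a fragment by a random chord.
#' @param texture greyscale band: `"white"`, `"gray"`, `"black"`, or
#'   `"mixed"` (drawn per image), matching the white/black/greyish look of
#'   phosphatized specimens.
#' @return object of class `taxon_spec`.
#' @export
taxon_spec <- function(family, size_mean = 0.75, size_jitter = 0.15,
                       shape_jitter = 0.35, fragmentation_prob = 0.25,
                       texture = "mixed") {
  family <- match.arg(family, .taxon_families)
  stopifnot(size_mean > 0, size_mean < 1, size_jitter >= 0,
            fragmentation_prob >= 0, fragmentation_prob <= 1)
  structure(list(family = family, size_mean = size_mean,
                 size_jitter = size_jitter, shape_jitter = shape_jitter,
                 fragmentation_prob = fragmentation_prob, texture = texture),
            class = "taxon_spec")
}

#' Default specifications for the nine-taxon benchmark
#'
#' The irregular-dross class uses the highest shape variability and
#' fragmentation -- deliberately the hardest class, as amorphous debris is
#' for real classifiers.
#'
#' @return named list of nine [taxon_spec()] objects.
#' @export
taxon_specs <- function() {
  sp <- lapply(.taxon_families, taxon_spec)
  names(sp) <- .taxon_families
  sp$irregular_dross$shape_jitter <- 0.9
  sp$irregular_dross$fragmentation_prob <- 0.4
  sp$sphere$size_mean <- 0.6
  sp
}

# Unit coordinate grids: x = columns, y = rows, both in [-1, 1].
.unit_grid <- function(side) {
  v <- (seq_len(side) - (side + 1) / 2) / (side / 2)
  list(x = matrix(v, side, side, byrow = TRUE),
       y = matrix(v, side, side))
}

.rot_coords <- function(g, angle_deg) {
  a <- angle_deg * pi / 180
  list(x = cos(a) * g$x + sin(a) * g$y,
       y = -sin(a) * g$x + cos(a) * g$y)
}

# Greyscale texture field: base level from the band, speckle, soft clip.
.texture_field <- function(side, band) {
  g0 <- runif(1, band[1], band[2])
  tex <- g0 + matrix(rnorm(side * side, sd = 12), side, side)
  pmin(pmax(tex, 15), 250)
}

# --- the nine family renderers (mask + multiplicative shading) -------------

.render_cone_tube <- function(g, s, jit) {
  hl <- s * 0.85
  bw <- s * 0.30 * (1 + jit * runif(1, -0.5, 0.5))
  bend <- jit * runif(1, -0.3, 0.3)
  t <- (g$y + hl) / (2 * hl)
  xo <- g$x - bend * s * t^2
  mask <- t >= 0 & t <= 1 & abs(xo) <= bw * t + 0.015
  list(mask = mask, shade = 1 - 0.35 * pmin(abs(xo) / (bw * pmax(t, 0.05)), 1)^2)
}

.render_sphere <- function(g, s, jit) {
  r <- s * 0.45
  d2 <- (g$x^2 + g$y^2) / r^2
  mask <- d2 <= 1
  list(mask = mask, shade = 0.6 + 0.4 * sqrt(pmax(1 - d2, 0)))
}

.render_cone_tower <- function(g, s, jit) {
  hl <- s * 0.85
  bw <- s * 0.34 * (1 + jit * runif(1, -0.4, 0.4))
  t <- (g$y + hl) / (2 * hl)
  steps <- ceiling(pmax(t, 1e-9) * 4) / 4  # four stacked segments
  mask <- t >= 0 & t <= 1 & abs(g$x) <= bw * (0.25 + 0.75 * steps)
  band <- (t * 4) %% 1 < 0.16
  list(mask = mask, shade = ifelse(band, 0.55, 1))
}

.render_curved_spine <- function(g, s, jit) {
  R <- s * 0.8
  cx <- -R * 0.75
  ang <- atan2(g$y, g$x - cx)
  a0 <- -0.5 - jit * runif(1, 0, 0.4)
  a1 <- 0.7 + jit * runif(1, 0, 0.4)
  t <- (ang - a0) / (a1 - a0)
  d <- sqrt((g$x - cx)^2 + g$y^2)
  tau <- s * 0.14 * (1 - 0.65 * pmin(pmax(t, 0), 1))
  mask <- t >= 0 & t <= 1 & abs(d - R) <= tau
  list(mask = mask, shade = 1 - 0.4 * (abs(d - R) / pmax(tau, 1e-9))^2)
}

.render_shell <- function(g, s, jit) {
  a <- s * 0.55
  b <- s * 0.40 * (1 + jit * runif(1, -0.3, 0.3))
  d2 <- (g$x / a)^2 + (g$y / b)^2
  mask <- d2 <= 1 & g$y <= b * 0.15
  ridge <- 1 - 0.3 * (0.5 + 0.5 * cos(10 * atan2(g$y - b * 0.15, g$x)))
  list(mask = mask, shade = ridge * (0.7 + 0.3 * sqrt(pmax(1 - d2, 0))))
}

.render_slotted_tube <- function(g, s, jit) {
  w <- s * 0.26
  hl <- s * 0.85
  taper <- 1 - 0.25 * (g$y + hl) / (2 * hl)
  mask <- abs(g$y) <= hl & abs(g$x) <= w * taper
  xs <- g$x / (w * pmax(taper, 1e-9))  # normalized across-tube coordinate
  slot <- pmin(abs(xs - 0.75), abs(xs - 0.25), abs(xs + 0.25), abs(xs + 0.75))
  list(mask = mask, shade = ifelse(slot < 0.10, 0.45, 1))
}

.render_worm <- function(g, s, jit) {
  hl <- s * 0.85
  A <- s * 0.18 * (1 + jit * runif(1, -0.5, 0.8))
  ph <- runif(1, 0, 2 * pi)
  tau <- s * 0.15
  mask <- abs(g$y) <= hl & abs(g$x - A * sin(3.4 * g$y / s + ph)) <= tau
  wrinkle <- 1 - 0.25 * (sin(22 * g$y / s) > 0.45)
  list(mask = mask, shade = wrinkle)
}

.render_segmented_tube <- function(g, s, jit) {
  w <- s * 0.20
  hl <- s * 0.9
  mask <- abs(g$y) <= hl & abs(g$x) <= w
  seg <- sin(pi * g$y / (s * 0.17))
  list(mask = mask, shade = ifelse(seg > 0.55, 0.55, 1) *
         (1 - 0.3 * (abs(g$x) / w)^2))
}

.render_irregular_dross <- function(g, s, jit) {
  k <- sample(3:6, 1)
  mask <- matrix(FALSE, nrow(g$x), ncol(g$x))
  for (i in seq_len(k)) {
    cx <- runif(1, -0.35, 0.35) * (0.5 + jit)
    cy <- runif(1, -0.35, 0.35) * (0.5 + jit)
    aa <- runif(1, 0.12, 0.5) * s
    bb <- runif(1, 0.12, 0.5) * s
    th <- runif(1, 0, pi)
    xr <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
    yr <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
    mask <- mask | ((xr / aa)^2 + (yr / bb)^2 <= 1)
  }
  list(mask = mask, shade = 0.7 + 0.3 * matrix(runif(length(g$x)),
                                               nrow(g$x), ncol(g$x)))
}

.taxon_renderers <- list(
  cone_tube = .render_cone_tube, sphere = .render_sphere,
  cone_tower = .render_cone_tower, curved_spine = .render_curved_spine,
  shell = .render_shell, slotted_tube = .render_slotted_tube,
  worm = .render_worm, segmented_tube = .render_segmented_tube,
  irregular_dross = .render_irregular_dross)

# Uniform blue field with +/-3 per-pixel sensor noise.
.blue_canvas <- function(side) {
  px <- array(0, c(side, side, 3L))
  for (ch in 1:3)
    px[, , ch] <- .BG_RGB[ch] + round(runif(side * side, -3, 3))
  px
}

.compose <- function(side, mask, tex) {
  px <- .blue_canvas(side)
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[mask] <- tex[mask]
    px[, , ch] <- pl
  }
  pmin(pmax(round(px), 0), 255)
}

#' Render one synthetic microfossil image
#'
#' A single fossil of the spec's family on the uniform blue background,
#' with seeded size, orientation, position and texture jitter and optional
#' chord-clipping fragmentation. Generation is pure: `(spec, side, seed)`
#' fully determine the pixels. With all jitters at zero the canonical
#' centred form is rendered; for the `sphere` family that is a centred disc
#' of radius `0.45 * size_mean` in frame units (frame spans `[-1, 1]`).
#'
#' @param spec a [taxon_spec()].
#' @param side image side in pixels, `>= 64`.
#' @param seed integer seed.
#' @return an [image_sample()] labelled with the family name.
#' @export
generate_taxon_image <- function(spec, side, seed) {
  stopifnot(inherits(spec, "taxon_spec"))
  if (side < 64) stop("side must be >= 64")
  renderer <- .taxon_renderers[[spec$family]]
  if (is.null(renderer)) stop("unknown family: ", spec$family)
  px <- .with_seed(seed, {
    s <- spec$size_mean * (1 + runif(1, -1, 1) * spec$size_jitter)
    s <- min(max(s, 0.08), 0.95)
    ox <- spec$shape_jitter * runif(1, -0.25, 0.25)
    oy <- spec$shape_jitter * runif(1, -0.25, 0.25)
    rot <- runif(1, -180, 180) * min(spec$shape_jitter * 2, 1)
    g <- .unit_grid(side)
    g <- list(x = g$x - ox, y = g$y - oy)
    g <- .rot_coords(g, rot)
    r <- renderer(g, s, spec$shape_jitter)
    mask <- r$mask
    if (runif(1) < spec$fragmentation_prob) {
      a <- runif(1, 0, 2 * pi)
      d <- runif(1, 0.15, 0.5) * s
      mask <- mask & (cos(a) * g$x + sin(a) * g$y <= d)
    }
    band_name <- if (spec$texture == "mixed")
      sample(names(.texture_bands), 1) else spec$texture
    tex <- .texture_field(side, .texture_bands[[band_name]]) * r$shade
    .compose(side, mask, tex)
  })
  image_sample(px, spec$family,
               source_path = sprintf("synthetic://%s/seed%d", spec$family, seed))
}

#' Generate the nine-class synthetic benchmark
#'
#' Balanced dataset of the nine shape families (one fossil per image, blue
#' background), mirroring the class structure of the real nine-taxon
#' collection. Deterministic given `seed`.
#'
#' @param n_per_class images per family, `>= 1`.
#' @param side image side in pixels (default 128, the desk-scale working
#'   side; use 1024 to match the acquisition geometry of real captures).
#' @param seed integer master seed.
#' @param specs taxon specifications (default [taxon_specs()]).
#' @return a `fossil_dataset` with `9 * n_per_class` samples.
#' @export
generate_benchmark <- function(n_per_class, side = 128, seed = 0,
                               specs = taxon_specs()) {
  stopifnot(n_per_class >= 1)
  samples <- vector("list", length(specs) * n_per_class)
  k <- 0L
  for (f in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      s <- generate_taxon_image(specs[[f]], side,
                                seed = as.integer(seed) + 7919L * f + i)
      s$source_path <- sprintf("synthetic://%s/%04d", specs[[f]]$family, i)
      samples[[k <- k + 1L]] <- s
    }
  }
  fossil_dataset(samples)
}

# --- source domain ----------------------------------------------------------
# Composite geometric/texture classes built from a primitive set disjoint
# from the taxon renderers. Each class is a fixed recipe (primitive,
# multiplicity, texture pattern) drawn once from the class seed; images of
# the class jitter around that recipe.

.source_primitives <- c("rect", "ring", "polygon", "cross", "dots",
                        "checker", "stripes", "wedge")

.render_primitive <- function(prim, g, s, extra) {
  switch(prim,
    rect = abs(g$x) <= s * extra$ar & abs(g$y) <= s / extra$ar,
    ring = {
      d <- sqrt(g$x^2 + g$y^2)
      d <= s & d >= s * extra$hole
    },
    polygon = {
      n <- extra$nsides
      inside <- matrix(TRUE, nrow(g$x), ncol(g$x))
      for (k in seq_len(n)) {
        th <- 2 * pi * k / n
        inside <- inside & (cos(th) * g$x + sin(th) * g$y <= s * 0.8)
      }
      inside
    },
    cross = (abs(g$x) <= s * 0.25 & abs(g$y) <= s) |
            (abs(g$y) <= s * 0.25 & abs(g$x) <= s),
    dots = {
      f <- extra$freq
      fx <- (g$x * f) %% 1 - 0.5
      fy <- (g$y * f) %% 1 - 0.5
      (fx^2 + fy^2 <= 0.09) & (g$x^2 + g$y^2 <= s^2)
    },
    checker = {
      f <- extra$freq
      (floor(g$x * f) + floor(g$y * f)) %% 2 == 0 &
        abs(g$x) <= s & abs(g$y) <= s
    },
    stripes = sin(g$x * extra$freq * pi) > 0.2 & abs(g$x) <= s & abs(g$y) <= s,
    wedge = {
      d <- sqrt(g$x^2 + g$y^2)
      ang <- atan2(g$y, g$x)
      d <= s & abs(ang) <= extra$span
    },
    stop("unknown primitive: ", prim))
}

.source_recipe <- function(class_seed) {
  .with_seed(class_seed, list(
    prim = sample(.source_primitives, 1),
    count = sample(1:3, 1),
    band = sample(names(.texture_bands), 1),
    pattern = sample(c("flat", "gradient", "bands"), 1),
    ar = runif(1, 0.4, 1.4),        # rect aspect
    hole = runif(1, 0.4, 0.75),     # ring hole fraction
    nsides = sample(3:7, 1),
    freq = sample(3:7, 1),
    span = runif(1, 0.4, 1.2)))
}

.render_source_image <- function(recipe, side) {
  g0 <- .unit_grid(side)
  mask <- matrix(FALSE, side, side)
  for (j in seq_len(recipe$count)) {
    s <- runif(1, 0.3, 0.6)
    ox <- runif(1, -0.3, 0.3)
    oy <- runif(1, -0.3, 0.3)
    g <- .rot_coords(list(x = g0$x - ox, y = g0$y - oy), runif(1, -180, 180))
    mask <- mask | .render_primitive(recipe$prim, g, s, recipe)
  }
  tex <- .texture_field(side, .texture_bands[[recipe$band]])
  if (recipe$pattern == "gradient")
    tex <- tex * (0.6 + 0.4 * (g0$x + 1) / 2)
  if (recipe$pattern == "bands")
    tex <- tex * (1 - 0.3 * (sin(g0$y * 8) > 0))
  .compose(side, mask, tex)
}

#' Generate a multi-class source domain for desk-scale pretraining
#'
#' Classes are composite geometric/texture recipes (rings, polygons,
#' crosses, dot grids, checkers, stripes, wedges...) rendered on the same
#' blue background and greyscale bands as the fossil benchmark, so source
#' and target share low-level statistics -- edges, curvature, texture --
#' while sharing no class renderer. This is the stand-in for pretraining on
#' a large natural-image collection.
#'
#' @param n_classes number of source classes, `>= 10` (default 20).
#' @param n_per_class images per class (default 100).
#' @param side image side in pixels (default 128).
#' @param seed integer master seed.
#' @return a `fossil_dataset` with classes `src01 ... srcNN`.
#' @export
generate_source_domain <- function(n_classes = 20, n_per_class = 100,
                                   side = 128, seed = 0) {
  if (n_classes < 10) stop("n_classes must be >= 10")
  samples <- vector("list", n_classes * n_per_class)
  k <- 0L
  for (cl in seq_len(n_classes)) {
    recipe <- .source_recipe(as.integer(seed) + 104729L + cl)
    for (i in seq_len(n_per_class)) {
      px <- .with_seed(as.integer(seed) + 7919L * (100L + cl) + i,
                       .render_source_image(recipe, side))
      samples[[k <- k + 1L]] <- image_sample(
        px, sprintf("src%02d", cl),
        source_path = sprintf("synthetic://src%02d/%04d", cl, i))
    }
  }
  fossil_dataset(samples)
}
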