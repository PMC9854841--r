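#' Construct a single labelled image sample
#'
#' The atomic record of the package: one RGB microscope image together with
#' its taxon label and provenance. Pixels are stored as a numeric
#' `H x W x 3` array of 8-bit intensities (0--255), rows = image rows.
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 255]`;
#'   `H, W >= 32`.
#' @param label taxon identifier (single string).
#' @param source_path provenance string; must be unique within a dataset.
#' @param split_tag one of `"train"`, `"test"`, `"unassigned"`.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(pixels, label, source_path = NA_character_,
                         split_tag = "unassigned") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (d[1] < 32L || d[2] < 32L)
    stop("image too small: need H >= 32 and W >= 32, got ", d[1], " x ", d[2])
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("label must be a single string")
  split_tag <- match.arg(split_tag, c("unassigned", "train", "test"))
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, label = label,
                 source_path = source_path, split_tag = split_tag),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_sample> %dx%d RGB, label '%s' [%s]\n",
              d[1], d[2], x$label, x$split_tag))
  invisible(x)
}

#' Assemble a labelled fossil image dataset
#'
#' @param samples list of [image_sample()] objects.
#' @param classes optional ordered character vector of taxon identifiers;
#'   defaults to the sorted unique sample labels. Class order is the
#'   label-to-index mapping used by every model in the package.
#' @return object of class `fossil_dataset` with fields `classes`,
#'   `samples` and `manifest` (data frame of path, label, split_tag).
#' @export
fossil_dataset <- function(samples, classes = NULL) {
  labels <- vapply(samples, function(s) s$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes))
    stop("sample labels not in class list: ",
         paste(setdiff(labels, classes), collapse = ", "))
  paths <- vapply(samples, function(s) s$source_path, character(1))
  known <- paths[!is.na(paths)]
  if (anyDuplicated(known))
    stop("duplicate source_path: ", known[duplicated(known)][1])
  manifest <- data.frame(
    path = paths,
    label = labels,
    split_tag = vapply(samples, function(s) s$split_tag, character(1)),
    stringsAsFactors = FALSE)
  structure(list(classes = classes, samples = samples, manifest = manifest),
            class = "fossil_dataset")
}

#' @export
print.fossil_dataset <- function(x, ...) {
  cat(sprintf("<fossil_dataset> %d samples, %d classes\n",
              length(x$samples), length(x$classes)))
  print(table(factor(x$manifest$label, levels = x$classes)))
  invisible(x)
}

#' Number of samples in a dataset
#' @param x a `fossil_dataset`.
#' @export
length.fossil_dataset <- function(x) length(x$samples)

.image_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

# EBImage stores frames as (x = width, y = height); the package convention is
# rows x cols, hence the aperm on every crossing of that boundary.
.read_pixels <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  px <- aperm(img[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  pmin(pmax(round(px * 255), 0), 255)
}

.write_pixels <- function(pixels, path) {
  img <- EBImage::Image(aperm(pixels / 255, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path)
}

#' Load a folder-per-class image dataset
#'
#' Reads a directory tree `root/<class>/<image>.{png,jpg,jpeg,tif,tiff}`
#' into a [fossil_dataset()]. Classes are ordered lexicographically by
#' folder name and files lexicographically within a class, so the manifest
#' is deterministic. Unreadable files are skipped with a warning and listed
#' in the `skipped` attribute.
#'
#' @param root dataset root directory.
#' @return a `fossil_dataset`.
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[order(basename(dirs))]
  if (length(dirs) == 0L) stop("no classes found in ", root)
  samples <- list()
  skipped <- character(0)
  for (d in dirs) {
    cls <- basename(d)
    files <- list.files(d, full.names = TRUE)
    files <- files[tolower(tools::file_ext(files)) %in% .image_exts]
    files <- files[order(basename(files))]
    for (f in files) {
      px <- tryCatch(.read_pixels(f), error = function(e) NULL)
      if (is.null(px)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        skipped <- c(skipped, f)
        next
      }
      samples[[length(samples) + 1L]] <- image_sample(px, cls, source_path = f)
    }
  }
  ds <- fossil_dataset(samples, classes = basename(dirs))
  attr(ds, "skipped") <- skipped
  ds
}

#' Save a dataset as a folder-per-class tree plus manifest
#'
#' Images are written as PNG (lossless, so save/load round-trips pixels
#' bit-exactly); the manifest goes to `manifest.csv` with columns
#' `path,label,split_tag`.
#'
#' @param ds a `fossil_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame as written.
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counter <- integer(0)
  rows <- vector("list", length(ds$samples))
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    cd <- file.path(dir, s$label)
    dir.create(cd, showWarnings = FALSE)
    k <- (counter[s$label] <- sum(counter[s$label], 1L, na.rm = TRUE))
    path <- file.path(cd, sprintf("%s_%04d.png", s$label, k))
    .write_pixels(s$pixels, path)
    rows[[i]] <- data.frame(path = path, label = s$label,
                            split_tag = s$split_tag, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest <- manifest[order(manifest$label, manifest$path), , drop = FALSE]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Balanced subset by per-class indices into ds$samples.
.subset_dataset <- function(ds, idx, split_tag = NULL) {
  samples <- ds$samples[idx]
  if (!is.null(split_tag))
    samples <- lapply(samples, function(s) { s$split_tag <- split_tag; s })
  fossil_dataset(samples, classes = ds$classes)
}

.class_indices <- function(ds) {
  labels <- vapply(ds$samples, function(s) s$label, character(1))
  lapply(stats::setNames(ds$classes, ds$classes), function(cl) which(labels == cl))
}

#' Split a dataset into a fixed balanced test set and a training pool
#'
#' Draws exactly `test_n_per_class` images of every taxon, uniformly at
#' random, to form the unique held-out test set; everything else becomes the
#' training pool. Membership is deterministic given `seed`, and the two
#' parts are disjoint by construction.
#'
#' @param ds a `fossil_dataset`.
#' @param test_n_per_class test images per class; every class must have
#'   strictly more samples than this.
#' @param seed integer seed for the split.
#' @return `list(train = , test = )` of `fossil_dataset`s.
#' @export
make_split <- function(ds, test_n_per_class, seed) {
  stopifnot(test_n_per_class >= 1)
  by_class <- .class_indices(ds)
  short <- names(by_class)[vapply(by_class, length, integer(1)) <= test_n_per_class]
  if (length(short) > 0L)
    stop("class '", short[1], "' has too few samples for test_n_per_class = ",
         test_n_per_class)
  test_idx <- .with_seed(seed, {
    unlist(lapply(by_class, function(ix) sort(sample(ix, test_n_per_class))),
           use.names = FALSE)
  })
  train_idx <- setdiff(seq_along(ds$samples), test_idx)
  list(train = .subset_dataset(ds, train_idx, "train"),
       test = .subset_dataset(ds, test_idx, "test"))
}

#' Draw repeated balanced training groups of varied size
#'
#' For every requested per-class training size, draws `n_groups`
#' independent balanced subsets of the training pool (the repeated-
#' subsampling protocol used to average recognition scores over groups).
#'
#' @param train training-pool `fossil_dataset`.
#' @param sizes integer vector of per-class training-set sizes,
#'   e.g. `c(1, 3, 5, 10, 50, 100, 200)`.
#' @param n_groups number of independent groups per size.
#' @param seed integer; group `g` of size index `i` uses the derived seed
#'   `seed + 1009*(i-1) + g`.
#' @return list of `sampling_plan` objects (one per size x group), each
#'   with fields `per_class_train_n`, `group_index`, `seed` and `indices`
#'   (per-class sample indices into `train`).
#' @export
sample_training_groups <- function(train, sizes, n_groups, seed) {
  by_class <- .class_indices(train)
  min_n <- min(vapply(by_class, length, integer(1)))
  if (max(sizes) > min_n)
    stop("requested size ", max(sizes), " exceeds smallest class count ", min_n)
  plans <- list()
  for (i in seq_along(sizes)) {
    for (g in seq_len(n_groups) - 1L) {
      plan_seed <- as.integer(seed) + 1009L * (i - 1L) + g
      idx <- .with_seed(plan_seed, {
        lapply(by_class, function(ix) sort(sample(ix, sizes[i])))
      })
      plans[[length(plans) + 1L]] <- structure(
        list(per_class_train_n = as.integer(sizes[i]), group_index = g,
             seed = plan_seed, indices = idx),
        class = "sampling_plan")
    }
  }
  plans
}

#' Materialize a sampling plan as a dataset
#'
#' @param train the training pool the plan was drawn from.
#' @param plan a `sampling_plan` from [sample_training_groups()].
#' @return balanced `fossil_dataset` with `per_class_train_n` samples per class.
#' @export
realize_plan <- function(train, plan) {
  .subset_dataset(train, unlist(plan$indices, use.names = FALSE), "train")
}
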