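# Synthetic food-image generator: labelled images with controllable colour,
# texture and shape signatures, single- and multi-category composites, and
# manifest writing.  Emulates the structure of a small photographic food
# record dataset (about ten categories, a handful of positive training
# images each, larger multi-label test sets) so the full pipeline can be
# exercised end to end without photographic data.

#' Define a synthetic food category
#'
#' @param name category name.
#' @param colour base RGB colour, each channel in `[0, 255]`.
#' @param jitter per-channel Gaussian colour jitter (standard deviation).
#' @param texture one of `"smooth"`, `"speckle"`, `"stripe"`, `"blob"`.
#' @param frequency texture spatial period/scale in pixels (ignored for
#'   `"smooth"`).
#' @param contrast texture contrast (relative amplitude, positive).
#' @param shape one of `"disc"`, `"ellipse"`, `"rod"`, `"heap"`.
#' @param size size (radius-like, pixels) range `c(min, max)` of rendered
#'   items.
#' @return an object of class `category_spec`.
#' @export
category_spec <- function(name, colour, jitter = 8,
                          texture = c("smooth", "speckle", "stripe", "blob"),
                          frequency = 6, contrast = 0.3,
                          shape = c("disc", "ellipse", "rod", "heap"),
                          size = c(16, 24)) {
  texture <- match.arg(texture)
  shape <- match.arg(shape)
  stopifnot(length(colour) == 3L, all(colour >= 0 & colour <= 255),
            jitter >= 0, frequency > 0, contrast > 0,
            length(size) == 2L, size[1L] > 0, size[2L] >= size[1L])
  structure(list(name = as.character(name), colour = as.numeric(colour),
                 jitter = jitter, texture = texture, frequency = frequency,
                 contrast = contrast, shape = shape, size = as.numeric(size)),
            class = "category_spec")
}

#' Default ten-category synthetic profile
#'
#' Ten food-like categories with distinct colour/texture/shape signatures.
#' Base colours sit at the centres of the colour channel's quantization bins
#' so that moderate jitter and mild illumination changes keep pixels within
#' their bins.  The last two categories ("berries_blue" and "berries_green")
#' are identical except for their base colour: they are separable only
#' through the colour channel, which makes them the designated probe pair
#' for colour-channel ablation.
#'
#' @param n number of categories to return (2..10, default 10).
#' @return a list of [category_spec()]s.
#' @export
default_category_specs <- function(n = 10L) {
  specs <- list(
    category_spec("tomato",   c(224, 32, 32),   texture = "speckle",
                  frequency = 5, contrast = 0.35, shape = "disc"),
    category_spec("peas",     c(32, 160, 32),   texture = "speckle",
                  frequency = 3, contrast = 0.6, shape = "heap"),
    category_spec("milk",     c(235, 235, 235), texture = "speckle",
                  frequency = 5, contrast = 0.1, shape = "ellipse", jitter = 4),
    category_spec("carrots",  c(224, 96, 32),   texture = "stripe",
                  frequency = 8, contrast = 0.45, shape = "rod"),
    category_spec("cheese",   c(230, 160, 40),  texture = "blob",
                  frequency = 5, contrast = 0.25, shape = "ellipse"),
    category_spec("custard",  c(224, 160, 96),  texture = "blob",
                  frequency = 8, contrast = 0.4, shape = "heap"),
    category_spec("plum",     c(96, 32, 160),   texture = "speckle",
                  frequency = 6, contrast = 0.6, shape = "disc"),
    category_spec("bread",    c(160, 96, 32),   texture = "blob",
                  frequency = 3, contrast = 0.6, shape = "disc"),
    category_spec("berries_blue",  c(32, 96, 224), texture = "speckle",
                  frequency = 4, contrast = 0.5, shape = "disc"),
    category_spec("berries_green", c(32, 224, 96), texture = "speckle",
                  frequency = 4, contrast = 0.5, shape = "disc"))
  stopifnot(n >= 2L, n <= length(specs))
  specs[seq_len(n)]
}

# Anti-aliased coverage mask (values in [0, 1]) for one item shape on an
# h x w canvas.  Uses the current RNG stream for random shape parameters.
shape_mask <- function(shape, h, w, cx, cy, r) {
  xs <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - cy, times = w), h, w)
  aa <- function(d, lim) pmin(pmax(lim + 0.5 - d, 0), 1)
  switch(shape,
    disc = aa(sqrt(xs^2 + ys^2), r),
    ellipse = {
      th <- stats::runif(1L, 0, pi)
      u <- cos(th) * xs + sin(th) * ys
      v <- -sin(th) * xs + cos(th) * ys
      aa(sqrt(u^2 + (v / 0.6)^2), r)
    },
    rod = {
      th <- stats::runif(1L, 0, pi)
      u <- cos(th) * xs + sin(th) * ys
      v <- -sin(th) * xs + cos(th) * ys
      # capsule: distance to a segment of half-length r, width 0.45 r
      d <- sqrt(pmax(abs(u) - r * 0.8, 0)^2 + v^2)
      aa(d, 0.45 * r)
    },
    heap = {
      m <- matrix(0, h, w)
      for (b in 1:3) {
        ox <- stats::runif(1L, -0.4, 0.4) * r
        oy <- stats::runif(1L, -0.4, 0.4) * r
        m <- pmax(m, aa(sqrt((xs - ox)^2 + (ys - oy)^2), 0.65 * r))
      }
      m
    })
}

# Multiplicative / additive texture fields over an h x w canvas.
texture_field <- function(spec, h, w) {
  mult <- matrix(1, h, w)
  add <- matrix(0, h, w)
  if (spec$texture == "speckle") {
    z <- gaussian_blur(matrix(stats::runif(h * w, -1, 1), h, w),
                       spec$frequency / 3)
    z <- z / max(stats::sd(z), 1e-9)
    mult <- 1 + spec$contrast * pmin(pmax(z, -2), 2) / 2
  } else if (spec$texture == "stripe") {
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ph <- stats::runif(1L, 0, 2 * pi)
    mult <- 1 + spec$contrast * sin(2 * pi * xs / spec$frequency + ph)
  } else if (spec$texture == "blob") {
    n_blob <- max(3L, as.integer(round(h * w / (6 * spec$frequency^2))))
    z <- matrix(0, h, w)
    z[cbind(sample.int(h, n_blob, replace = TRUE),
            sample.int(w, n_blob, replace = TRUE))] <-
      stats::runif(n_blob, -1, 1)
    z <- gaussian_blur(z, spec$frequency / 2)
    z <- z / max(abs(z), 1e-9)
    add <- spec$contrast * 160 * z
  }
  list(mult = mult, add = add)
}

#' Render one food item onto a canvas
#'
#' Draws a single item: anti-aliased shape mask filled with the base colour
#' plus per-pixel jitter, texture overlaid (multiplicative for stripes and
#' speckle, additive for blobs).  Consumes the current RNG stream, so it is
#' deterministic given the RNG state.
#'
#' @param canvas numeric `H x W x 3` array of values in `[0, 255]`.
#' @param spec a [category_spec()].
#' @param position item centre `c(x, y)` (1-based pixel coordinates).
#' @param size item size (radius-like, pixels); defaults to a draw from the
#'   spec's size range.
#' @return the canvas with the item composited in.
#' @export
render_item <- function(canvas, spec, position, size = NULL) {
  stopifnot(inherits(spec, "category_spec"), length(position) == 2L)
  h <- dim(canvas)[1L]; w <- dim(canvas)[2L]
  if (position[1L] < 1 || position[1L] > w || position[2L] < 1 ||
      position[2L] > h)
    stop("item position outside canvas")
  r <- size %||% stats::runif(1L, spec$size[1L], spec$size[2L])
  if (2 * r + 2 > min(h, w)) stop("item larger than canvas")
  mask <- shape_mask(spec$shape, h, w, position[1L], position[2L], r)
  tex <- texture_field(spec, h, w)
  for (ch in 1:3) {
    col_px <- spec$colour[ch] +
      matrix(stats::rnorm(h * w, 0, spec$jitter), h, w)
    item <- pmin(pmax(col_px * tex$mult + tex$add, 0), 255)
    canvas[, , ch] <- canvas[, , ch] * (1 - mask) + item * mask
  }
  canvas
}

#' Generate one synthetic food image
#'
#' Places one item per spec (up to five distinct specs) at non-overlapping
#' random positions on a weakly textured neutral background, optionally
#' applies a global illumination scaling, and returns the image with its
#' label set.  Item sizes shrink automatically with the number of items so
#' composites fit the canvas.
#'
#' @param specs a [category_spec()] or list of up to five distinct specs.
#' @param size canvas side length in pixels (default 128).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param illumination range of the global illumination scale factor
#'   (default `c(1, 1)`, i.e. none); values are drawn uniformly.
#' @param bg_level background grey level (default 110, chosen away from the
#'   colour quantization edges so mild illumination changes do not flip the
#'   whole background between colour bins).
#' @param bg_noise background texture amplitude (default 4).
#' @return a list with `record` (an [image_record()] carrying the label
#'   set) and `labels`.
#' @export
generate_image <- function(specs, size = 128L, seed = NULL,
                           illumination = c(1, 1), bg_level = 110,
                           bg_noise = 4) {
  if (inherits(specs, "category_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, character(1L), "name")
  if (length(specs) < 1L || length(specs) > 5L || anyDuplicated(nm))
    stop("specs must be 1..5 distinct category specs")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  h <- w <- as.integer(size)
  # weakly textured grey background so interest points exist everywhere but
  # concentrate on the items
  bg <- gaussian_blur(matrix(stats::rnorm(h * w, 0, 3 * bg_noise), h, w), 1.2)
  canvas <- array(rep(pmin(pmax(bg_level + bg, 0), 255), 3L),
                  dim = c(h, w, 3L))
  shrink <- c(1, 0.85, 0.7, 0.6, 0.55)[length(specs)]
  placed <- matrix(numeric(0), 0L, 3L)   # x, y, r
  for (sp in specs) {
    r <- stats::runif(1L, sp$size[1L], sp$size[2L]) * shrink
    ok <- FALSE
    for (attempt in 1:100) {
      cx <- stats::runif(1L, r + 2, w - r - 1)
      cy <- stats::runif(1L, r + 2, h - r - 1)
      if (nrow(placed) == 0L ||
          all(sqrt((placed[, 1L] - cx)^2 + (placed[, 2L] - cy)^2) >
              placed[, 3L] + r + 2)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place item '", sp$name,
                  "' without overlap after 100 attempts")
    canvas <- render_item(canvas, sp, c(cx, cy), size = r)
    placed <- rbind(placed, c(cx, cy, r))
  }
  sc <- stats::runif(1L, illumination[1L], illumination[2L])
  canvas <- pmin(pmax(round(canvas * sc), 0), 255)
  list(record = image_record(canvas, labels = nm), labels = nm)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes PNG images and a manifest CSV emulating a small food-record
#' dataset: single-label training images and a test set in which a stated
#' fraction of images are multi-label composites (up to five categories).
#' Fully reproducible from the seed: the same seed yields byte-identical
#' images and manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param n_categories number of categories (>= 2; default 10).
#' @param train_per_category scalar or `c(min, max)` range of positive
#'   training images per category (default `c(4, 8)`).
#' @param test_per_category scalar or range of test images owned by each
#'   category (default `c(13, 20)`).
#' @param multi_label_fraction fraction of test images that are multi-label
#'   composites (default 0.3).
#' @param seed integer seed (default 1).
#' @param size canvas side length in pixels (default 128).
#' @param specs list of [category_spec()]s; defaults to
#'   [default_category_specs()].
#' @param illumination global illumination scale range
#'   (default `c(0.95, 1.05)`).
#' @return the manifest `data.frame` (columns `image_path`, `labels`,
#'   `split`, plus `abs_path`), invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(out_dir, n_categories = 10L,
                             train_per_category = c(4L, 8L),
                             test_per_category = c(13L, 20L),
                             multi_label_fraction = 0.3, seed = 1L,
                             size = 128L,
                             specs = default_category_specs(n_categories),
                             illumination = c(0.95, 1.05)) {
  stopifnot(n_categories >= 2L, length(specs) == n_categories,
            multi_label_fraction >= 0, multi_label_fraction <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  draw_n <- function(spec_n) {
    if (length(spec_n) == 1L) rep(as.integer(spec_n), n_categories)
    else sample(seq(spec_n[1L], spec_n[2L]), n_categories, replace = TRUE)
  }
  n_train <- draw_n(train_per_category)
  n_test <- draw_n(test_per_category)
  nm <- vapply(specs, `[[`, character(1L), "name")

  rows <- list(); img_id <- 0L
  emit <- function(spec_idx, split) {
    img_id <<- img_id + 1L
    img_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    gen <- generate_image(specs[spec_idx], size = size, seed = img_seed,
                          illumination = illumination)
    fn <- sprintf("img_%04d.png", img_id)
    png::writePNG(gen$record$pixels / 255, file.path(out_dir, fn))
    rows[[length(rows) + 1L]] <<- data.frame(
      image_path = fn, labels = paste(sort(gen$labels), collapse = ";"),
      split = split, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(n_categories))
    for (k in seq_len(n_train[ci])) emit(ci, "train")

  owners <- rep(seq_len(n_categories), n_test)
  n_multi <- round(multi_label_fraction * length(owners))
  multi_rows <- if (n_multi > 0L)
    sort(sample.int(length(owners), n_multi)) else integer(0)
  for (ti in seq_along(owners)) {
    ci <- owners[ti]
    idx <- ci
    if (ti %in% multi_rows) {
      n_extra <- sample(1:4, 1L, prob = c(0.7, 0.2, 0.07, 0.03))
      idx <- c(ci, sample(setdiff(seq_len(n_categories), ci),
                          min(n_extra, n_categories - 1L)))
    }
    emit(idx, "test")
  }

  man <- do.call(rbind, rows)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man$abs_path <- file.path(out_dir, man$image_path)
  attr(man, "seed") <- as.integer(seed)
  attr(man, "specs") <- specs
  invisible(man)
}
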