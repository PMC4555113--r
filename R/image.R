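#' Construct an image record
#'
#' The pipeline's working representation of a photograph: an H x W x 3 array
#' of 8-bit RGB values in `[0, 255]`, a source path, and an optional set of
#' ground-truth category labels.
#'
#' @param pixels numeric array `H x W x 3` (RGB, values in `[0, 255]`), or an
#'   `H x W` greyscale matrix which is replicated to three channels.
#' @param path source file path (informational).
#' @param labels character vector of category labels; may be empty for
#'   unlabeled prediction inputs.
#' @return an object of class `image_record` with fields `path`, `pixels`
#'   and `labels`.
#' @export
image_record <- function(pixels, path = NA_character_, labels = character()) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("pixels must be an H x W x 3 array or an H x W matrix")
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("zero-area image")
  rng <- range(pixels)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(path = path, pixels = pixels,
                 labels = unique(as.character(labels))),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record> %d x %d px, labels: %s\n  path: %s\n",
              d[1L], d[2L],
              if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)",
              x$path))
  invisible(x)
}

#' Load a PNG or JPEG image as an image record
#'
#' Decodes an image file to the pipeline's 8-bit RGB representation.
#' Greyscale images are replicated to three channels and any alpha channel is
#' dropped.  The format is sniffed from the file's magic bytes, falling back
#' to the file extension.
#'
#' @param path path to a PNG or JPEG file.
#' @param labels optional ground-truth labels to attach.
#' @return an [image_record()].
#' @export
load_image <- function(path, labels = character()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file: ", path)
  magic <- tryCatch(readBin(path, "raw", n = 3L), error = function(e) raw(0))
  kind <- if (length(magic) >= 3L && magic[1L] == as.raw(0x89) &&
              magic[2L] == as.raw(0x50)) "png"
          else if (length(magic) >= 2L && magic[1L] == as.raw(0xff) &&
                   magic[2L] == as.raw(0xd8)) "jpeg"
          else switch(tolower(tools::file_ext(path)),
                      png = "png", jpg = , jpeg = "jpeg", NA_character_)
  if (is.na(kind))
    stop("unsupported or corrupt image file (expected PNG or JPEG): ", path)
  if (kind == "jpeg") {
    # libjpeg silently grey-pads truncated streams; require the EOI marker
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    seek(con, max(file.size(path) - 2L, 0))
    tail2 <- readBin(con, "raw", n = 2L)
    if (length(tail2) < 2L || tail2[1L] != as.raw(0xff) ||
        tail2[2L] != as.raw(0xd9))
      stop("cannot decode image file (truncated JPEG stream): ", path)
  }
  arr <- tryCatch(
    if (kind == "png") png::readPNG(path) else jpeg::readJPEG(path),
    error = function(e) stop("cannot decode image file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  nc <- dim(arr)[3L]
  if (nc == 2L) arr <- arr[, , 1L, drop = FALSE]        # grey + alpha
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]       # drop alpha
  if (dim(arr)[3L] == 1L) arr <- array(rep(arr, 3L), dim = c(dim(arr)[1:2], 3L))
  image_record(round(arr * 255), path = path, labels = labels)
}

#' Conditionally downscale a large image by a factor of two
#'
#' If either dimension exceeds `threshold` pixels (default 2000), both
#' dimensions are halved once by area averaging (each output pixel is the
#' mean of a 2x2 input block); odd trailing rows/columns are dropped
#' (floor division).  The rule is applied once, never iterated, and images
#' at or below the threshold pass through unchanged.
#'
#' @param image an [image_record()].
#' @param threshold dimension above which the image is downscaled.
#' @return an [image_record()], downscaled if triggered.
#' @export
maybe_downscale <- function(image, threshold = 2000L) {
  stopifnot(inherits(image, "image_record"), threshold > 0)
  d <- dim(image$pixels)
  if (d[1L] <= threshold && d[2L] <= threshold) return(image)
  h2 <- d[1L] %/% 2L
  w2 <- d[2L] %/% 2L
  px <- image$pixels[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  ri <- seq(1L, 2L * h2, by = 2L)
  ci <- seq(1L, 2L * w2, by = 2L)
  out <- (px[ri, ci, , drop = FALSE] + px[ri + 1L, ci, , drop = FALSE] +
          px[ri, ci + 1L, , drop = FALSE] + px[ri + 1L, ci + 1L, , drop = FALSE]) / 4
  image_record(round(out), path = image$path, labels = image$labels)
}

# Greyscale intensity as the per-pixel channel mean, in [0, 255].
as_grey <- function(image) {
  (image$pixels[, , 1L] + image$pixels[, , 2L] + image$pixels[, , 3L]) / 3
}
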