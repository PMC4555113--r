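# Per-interest-point feature descriptors for the three channels:
#   shape   - 128-dim histogram of gradient orientations (4x4 spatial grid x
#             8 orientation bins) over a scale- and orientation-normalized
#             patch, L2-normalized with the standard 0.2 clamp;
#   texture - 59-bin uniform LBP(8,1) histogram over a scale-adaptive patch,
#             L1-normalized;
#   colour  - joint 4x4x4 quantized RGB histogram over the same patch
#             geometry, L1-normalized.
# Descriptor lists are index-aligned with the interest-point list.

CHANNELS <- c("shape", "texture", "colour")
CHANNEL_DIMS <- c(shape = 128L, texture = 59L, colour = 64L)

validate_points <- function(points, h, w) {
  if (!is.data.frame(points) ||
      !all(c("x", "y", "scale", "orientation") %in% names(points)))
    stop("points must be a data.frame with columns x, y, scale, orientation")
  if (nrow(points) == 0L) return(invisible(points))
  if (any(points$x < 0 | points$x > w - 1 | points$y < 0 | points$y > h - 1))
    stop("interest point outside image bounds")
  if (any(points$scale <= 0)) stop("interest point scale must be positive")
  invisible(points)
}

# ---- shape channel (gradient-orientation descriptor) ----------------------

#' Gradient-orientation shape descriptors
#'
#' Computes one 128-dimensional descriptor per interest point: gradients of
#' the greyscale intensity (channel mean) are sampled on a patch scaled by
#' the point's scale and rotated to its orientation, accumulated by trilinear
#' interpolation into a 4x4 spatial grid of 8-bin orientation histograms,
#' L2-normalized, clamped at 0.2 and renormalized.
#'
#' @param image an [image_record()].
#' @param points interest points as returned by [detect_interest_points()].
#' @return a numeric matrix with `nrow(points)` rows and 128 columns; all
#'   entries non-negative, rows of unit Euclidean norm.
#' @export
shape_descriptors <- function(image, points) {
  g <- as_grey(image) / 255
  h <- nrow(g); w <- ncol(g)
  validate_points(points, h, w)
  n <- nrow(points)
  out <- matrix(0, n, 128L)
  if (n == 0L) return(out)

  # gradients of the image smoothed to (approximately) each point's scale;
  # scales are grouped on a third-octave grid so each level is blurred once
  lev <- round(log2(pmax(points$scale, 0.8) / 1.6) * 3) / 3
  grads <- new.env(parent = emptyenv())
  get_grad <- function(l) {
    key <- sprintf("%.4f", l)
    if (is.null(grads[[key]])) {
      sb <- 1.6 * 2^l
      gm <- gaussian_blur(g, sqrt(max(sb^2 - 0.25, 0.01)))
      gx <- 0.5 * (gm[, c(2:w, w), drop = FALSE] - gm[, c(1L, 1:(w - 1L)), drop = FALSE])
      gy <- 0.5 * (gm[c(2:h, h), , drop = FALSE] - gm[c(1L, 1:(h - 1L)), , drop = FALSE])
      grads[[key]] <- list(mag = sqrt(gx^2 + gy^2),
                           ang = atan2(gy, gx) %% (2 * pi))
    }
    grads[[key]]
  }

  for (p in seq_len(n)) {
    x <- points$x[p]; y <- points$y[p]
    sc <- points$scale[p]; th <- points$orientation[p]
    gr <- get_grad(lev[p])
    hw <- 3 * sc                                   # histogram bin width, px
    rad <- as.integer(ceiling(hw * 2.5 * sqrt(2))) # support radius
    cx <- as.integer(round(x)); cy <- as.integer(round(y))
    ci <- max(1L, cx + 1L - rad):min(w, cx + 1L + rad)   # 1-based cols
    ri <- max(1L, cy + 1L - rad):min(h, cy + 1L + rad)   # 1-based rows
    rx <- rep(ci - 1 - x, each = length(ri))
    ry <- rep(ri - 1 - y, times = length(ci))
    cr <- cos(th); sr <- sin(th)
    xr <- (cr * rx + sr * ry) / hw
    yr <- (-sr * rx + cr * ry) / hw
    rbin <- yr + 1.5; cbin <- xr + 1.5
    keep <- rbin > -1 & rbin < 4 & cbin > -1 & cbin < 4
    if (!any(keep)) next
    mag <- as.vector(gr$mag[ri, ci, drop = FALSE])[keep]
    ang <- as.vector(gr$ang[ri, ci, drop = FALSE])[keep]
    wgt <- exp(-(xr[keep]^2 + yr[keep]^2) / 8) * mag
    obin <- ((ang - th) %% (2 * pi)) / (pi / 4)
    rb <- rbin[keep]; cb <- cbin[keep]
    r0 <- floor(rb); c0 <- floor(cb); o0 <- floor(obin)
    fr <- rb - r0; fc <- cb - c0; fo <- obin - o0
    vec <- numeric(128L)
    for (dr in 0:1) for (dc in 0:1) for (dd in 0:1) {
      rr <- r0 + dr; cc <- c0 + dc; oo <- (o0 + dd) %% 8
      sel <- rr >= 0 & rr <= 3 & cc >= 0 & cc <= 3
      if (!any(sel)) next
      ww <- wgt[sel] *
        (if (dr) fr[sel] else 1 - fr[sel]) *
        (if (dc) fc[sel] else 1 - fc[sel]) *
        (if (dd) fo[sel] else 1 - fo[sel])
      idx <- rr[sel] * 32 + cc[sel] * 8 + oo[sel] + 1
      acc <- rowsum(ww, idx)
      ii <- as.integer(rownames(acc))
      vec[ii] <- vec[ii] + acc[, 1L]
    }
    nv <- sqrt(sum(vec^2))
    if (nv > 0) {
      vec <- pmin(vec / nv, 0.2)
      vec <- vec / sqrt(sum(vec^2))
    }
    out[p, ] <- vec
  }
  out
}

# ---- texture channel (uniform LBP) ----------------------------------------

# Map each 8-bit LBP code to its uniform-pattern bin: codes with at most two
# circular 0/1 transitions get bins 1..58 (ascending code order); all other
# codes share bin 59.
lbp_uniform_map <- local({
  codes <- 0:255
  bits <- sapply(codes, function(z) as.integer(intToBits(z)[1:8]))
  trans <- colSums(abs(bits - bits[c(2:8, 1L), ]))
  map <- integer(256L)
  map[trans <= 2] <- seq_len(sum(trans <= 2))
  map[trans > 2] <- 59L
  map
})

# 8-neighbour LBP codes (strict 'neighbour > centre' comparison) for interior
# pixels; returns an (H-2) x (W-2) matrix of uniform bins in 1..59.
lbp_bins <- function(grey) {
  h <- nrow(grey); w <- ncol(grey)
  if (h < 3L || w < 3L) return(matrix(integer(0), 0L, 0L))
  ctr <- grey[2:(h - 1L), 2:(w - 1L), drop = FALSE]
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L),
               c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))
  code <- matrix(0L, h - 2L, w - 2L)
  for (b in seq_along(offs)) {
    di <- offs[[b]][1L]; dj <- offs[[b]][2L]
    nb <- grey[(2:(h - 1L)) + di, (2:(w - 1L)) + dj, drop = FALSE]
    code <- code + (nb > ctr) * 2L^(b - 1L)
  }
  matrix(lbp_uniform_map[code + 1L], h - 2L, w - 2L)
}

# Shared scale-adaptive patch geometry for the texture and colour channels:
# a square of side max(16, round(12 * scale)) centred on the point, clipped
# to the image.  Returns 1-based row/col index ranges.
patch_extent <- function(x, y, scale, h, w) {
  side <- max(16L, as.integer(round(12 * scale)))
  half <- side %/% 2L
  r0 <- as.integer(round(y)) + 1L - half
  c0 <- as.integer(round(x)) + 1L - half
  list(rows = max(1L, r0):min(h, r0 + side - 1L),
       cols = max(1L, c0):min(w, c0 + side - 1L))
}

#' Uniform local binary pattern texture descriptors
#'
#' Computes one 59-bin uniform LBP(8,1) histogram per interest point over a
#' square patch of side `max(16, round(12 * scale))` centred on the point
#' and clipped to the image, L1-normalized.  The LBP comparison is strict
#' (`neighbour > centre`), so constant patches map to the all-zeros uniform
#' pattern; the code is invariant to monotone intensity shifts.
#'
#' @inheritParams shape_descriptors
#' @return a numeric matrix with `nrow(points)` rows and 59 columns; rows
#'   are non-negative and sum to 1.
#' @export
texture_descriptors <- function(image, points) {
  g <- as_grey(image)
  h <- nrow(g); w <- ncol(g)
  validate_points(points, h, w)
  n <- nrow(points)
  out <- matrix(0, n, 59L)
  if (n == 0L) return(out)
  bins <- lbp_bins(g)     # bins for pixels 2..H-1 x 2..W-1
  for (p in seq_len(n)) {
    ext <- patch_extent(points$x[p], points$y[p], points$scale[p], h, w)
    rows <- ext$rows[ext$rows >= 2L & ext$rows <= h - 1L] - 1L
    cols <- ext$cols[ext$cols >= 2L & ext$cols <= w - 1L] - 1L
    if (length(rows) && length(cols)) {
      cnt <- tabulate(bins[rows, cols], nbins = 59L)
      out[p, ] <- cnt / sum(cnt)
    } else out[p, 1L] <- 1    # degenerate patch: flat texture
  }
  out
}

# ---- colour channel -------------------------------------------------------

# Joint 4x4x4 quantized RGB bin index (1..64, R-major) per pixel.
colour_bin_index <- function(pixels) {
  q <- function(ch) pmin(ch %/% 64, 3)
  q(pixels[, , 1L]) * 16 + q(pixels[, , 2L]) * 4 + q(pixels[, , 3L]) + 1
}

#' Quantized colour descriptors at interest points
#'
#' Computes one joint 4x4x4 = 64-bin RGB histogram per interest point (each
#' channel quantized into the four equal bins `[0,64)`, `[64,128)`,
#' `[128,192)`, `[192,256)`) over the same scale-adaptive patch geometry as
#' [texture_descriptors()], L1-normalized.  Bins are laid out R-major: bin
#' index = `16 * R_bin + 4 * G_bin + B_bin` (0-based).
#'
#' @inheritParams shape_descriptors
#' @return a numeric matrix with `nrow(points)` rows and 64 columns; rows
#'   are non-negative and sum to 1.
#' @export
colour_descriptors <- function(image, points) {
  h <- dim(image$pixels)[1L]; w <- dim(image$pixels)[2L]
  validate_points(points, h, w)
  n <- nrow(points)
  out <- matrix(0, n, 64L)
  if (n == 0L) return(out)
  qi <- colour_bin_index(image$pixels)
  for (p in seq_len(n)) {
    ext <- patch_extent(points$x[p], points$y[p], points$scale[p], h, w)
    cnt <- tabulate(qi[ext$rows, ext$cols], nbins = 64L)
    out[p, ] <- cnt / sum(cnt)
  }
  out
}

#' Whole-image quantized colour histogram
#'
#' The same joint 64-bin quantized RGB histogram as [colour_descriptors()],
#' computed over every pixel of the image.  Kept as a faithful global-colour
#' summary; the default pipeline uses the per-point colour descriptors so
#' that the colour channel can feed a codebook of its own.
#'
#' @param image an [image_record()].
#' @return a numeric vector of length 64, non-negative, summing to 1.
#' @export
colour_histogram_global <- function(image) {
  qi <- colour_bin_index(image$pixels)
  cnt <- tabulate(qi, nbins = 64L)
  cnt / sum(cnt)
}

# ---- combined feature set -------------------------------------------------

#' Extract the full per-image feature set
#'
#' Runs interest-point detection and all three descriptor channels, keeping
#' the per-channel descriptor matrices index-aligned with the point list.
#'
#' @param image an [image_record()].
#' @param channels channels to compute (default all three).
#' @param downscale apply [maybe_downscale()] first (default TRUE).
#' @return an object of class `bow_features`: a list with the `points`
#'   data.frame and one descriptor matrix per requested channel.
#' @export
extract_features <- function(image, channels = CHANNELS, downscale = TRUE) {
  stopifnot(all(channels %in% CHANNELS), length(channels) >= 1L)
  if (downscale) image <- maybe_downscale(image)
  pts <- detect_interest_points(image)
  out <- list(points = pts)
  if ("shape" %in% channels)   out$shape   <- shape_descriptors(image, pts)
  if ("texture" %in% channels) out$texture <- texture_descriptors(image, pts)
  if ("colour" %in% channels)  out$colour  <- colour_descriptors(image, pts)
  structure(out, class = "bow_features")
}

#' @export
print.bow_features <- function(x, ...) {
  cat(sprintf("<bow_features> %d interest points; channels: %s\n",
              nrow(x$points),
              paste(intersect(CHANNELS, names(x)), collapse = ", ")))
  invisible(x)
}
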