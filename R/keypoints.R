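# Difference-of-Gaussian interest point detection.
#
# Scale-space extrema of the DoG pyramid with sub-pixel/sub-scale refinement,
# low-contrast rejection, edge-response rejection (principal-curvature ratio)
# and a dominant gradient orientation per point.  Everything is deterministic
# for a fixed image.

# Separable Gaussian blur with replicate padding.
gaussian_blur <- function(m, sigma) {
  if (sigma < 1e-6) return(m)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # vertical pass
  pad <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  acc <- matrix(0, h, w)
  for (t in seq_along(k))
    acc <- acc + k[t] * pad[t:(t + h - 1L), , drop = FALSE]
  # horizontal pass
  pad <- acc[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  acc <- matrix(0, h, w)
  for (t in seq_along(k))
    acc <- acc + k[t] * pad[, t:(t + w - 1L), drop = FALSE]
  acc
}

# Shift a matrix by (di, dj) with replicate padding.
shift_mat <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + di, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dj, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Max / min over the full 3x3 neighbourhood (centre included).
neigh9 <- function(m, op) {
  v <- op(shift_mat(m, -1L, 0L), m, shift_mat(m, 1L, 0L))
  op(shift_mat(v, 0L, -1L), v, shift_mat(v, 0L, 1L))
}

# Bilinear 2x upsampling (used to recover fine-scale structure by adding a
# -1 octave, standard practice for scale-space detection on small images).
upsample2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- (seq_len(2L * h) + 1) / 2
  i0 <- pmin(floor(ri), h); i1 <- pmin(i0 + 1, h); fr <- ri - floor(ri)
  m <- m[i0, , drop = FALSE] * (1 - fr) + m[i1, , drop = FALSE] * fr
  ci <- (seq_len(2L * w) + 1) / 2
  j0 <- pmin(floor(ci), w); j1 <- pmin(j0 + 1, w); fc <- ci - floor(ci)
  m[, j0, drop = FALSE] * rep(1 - fc, each = 2L * h) +
    m[, j1, drop = FALSE] * rep(fc, each = 2L * h)
}

# Max / min over the 8 neighbours, centre excluded.
neigh8 <- function(m, op) {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    s <- shift_mat(m, di, dj)
    out <- if (is.null(out)) s else op(out, s)
  }
  out
}

#' Detect difference-of-Gaussian interest points
#'
#' Builds a Gaussian scale-space pyramid on the greyscale intensity (channel
#' mean), locates extrema of the difference-of-Gaussian response over space
#' and scale, refines them to sub-pixel accuracy, rejects low-contrast and
#' edge-like responses, and assigns each surviving point its dominant local
#' gradient orientation.  Constant images legitimately yield zero points.
#'
#' @param image an [image_record()].
#' @param n_scales number of scale samples per octave (default 3).
#' @param sigma0 base smoothing scale of each octave in pixels (default 1.6).
#' @param contrast_thr contrast threshold on the refined DoG response;
#'   applied as `contrast_thr / n_scales` (default 0.02, intensities in
#'   `[0, 1]`; a permissive setting suited to low-contrast food surfaces).
#' @param edge_ratio maximum allowed ratio of principal curvatures
#'   (default 10).
#' @param upsample start the pyramid one octave below the image (bilinear
#'   2x upsampling), which recovers fine-scale structure; defaults to TRUE
#'   for images whose smaller dimension is at most 512 pixels.
#' @return a `data.frame` with one row per point and columns `x`, `y`
#'   (0-based pixel coordinates, `x` = column), `scale` (pixels) and
#'   `orientation` (radians in `[0, 2*pi)`), ordered by `(y, x, scale)`.
#' @export
detect_interest_points <- function(image, n_scales = 3L, sigma0 = 1.6,
                                   contrast_thr = 0.02, edge_ratio = 10,
                                   upsample = NULL) {
  stopifnot(inherits(image, "image_record"))
  g <- as_grey(image) / 255
  h <- nrow(g); w <- ncol(g)
  if (is.null(upsample)) upsample <- min(h, w) <= 512L
  if (min(h, w) < 16L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      scale = numeric(0), orientation = numeric(0)))
  coord_mult <- 1
  init_blur <- 0.5            # assumed camera blur of the stored image
  if (upsample) {
    g <- upsample2(g)
    h <- nrow(g); w <- ncol(g)
    coord_mult <- 0.5
    init_blur <- 1
  }
  n_oct <- max(1L, as.integer(floor(log2(min(h, w)))) - 3L)
  s <- as.integer(n_scales)
  peak_thr <- contrast_thr / s
  border <- 5L
  # lift the base image to sigma0
  base <- gaussian_blur(g, sqrt(max(sigma0^2 - init_blur^2, 0.01)))
  sig <- sigma0 * 2^((0:(s + 2L)) / s)      # sigma of gaussian layer i (1-based)
  out <- vector("list", 64L)
  n_out <- 0L

  for (o in seq_len(n_oct)) {
    gauss <- vector("list", s + 3L)
    gauss[[1L]] <- base
    for (i in 2:(s + 3L))
      gauss[[i]] <- gaussian_blur(gauss[[i - 1L]],
                                  sqrt(sig[i]^2 - sig[i - 1L]^2))
    dog <- lapply(seq_len(s + 2L), function(i) gauss[[i + 1L]] - gauss[[i]])
    ho <- nrow(base); wo <- ncol(base)
    grad_cache <- new.env(parent = emptyenv())

    for (l in 2:(s + 1L)) {
      d0 <- dog[[l]]
      nb_max <- pmax(neigh8(d0, pmax), neigh9(dog[[l - 1L]], pmax),
                     neigh9(dog[[l + 1L]], pmax))
      nb_min <- pmin(neigh8(d0, pmin), neigh9(dog[[l - 1L]], pmin),
                     neigh9(dog[[l + 1L]], pmin))
      cand <- (d0 > nb_max | d0 < nb_min) & abs(d0) > 0.5 * peak_thr
      cand[c(seq_len(border), (ho - border + 1L):ho), ] <- FALSE
      cand[, c(seq_len(border), (wo - border + 1L):wo)] <- FALSE
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx) == 0L) next

      for (q in seq_len(nrow(idx))) {
        i <- idx[q, 1L]; j <- idx[q, 2L]; li <- l
        off <- NULL; dD <- NULL; Hxy <- NULL
        for (iter in 1:5) {
          D <- dog[[li]]
          dD <- 0.5 * c(D[i, j + 1L] - D[i, j - 1L],
                        D[i + 1L, j] - D[i - 1L, j],
                        dog[[li + 1L]][i, j] - dog[[li - 1L]][i, j])
          dxx <- D[i, j + 1L] + D[i, j - 1L] - 2 * D[i, j]
          dyy <- D[i + 1L, j] + D[i - 1L, j] - 2 * D[i, j]
          dss <- dog[[li + 1L]][i, j] + dog[[li - 1L]][i, j] - 2 * D[i, j]
          dxy <- 0.25 * (D[i + 1L, j + 1L] - D[i + 1L, j - 1L] -
                         D[i - 1L, j + 1L] + D[i - 1L, j - 1L])
          dxs <- 0.25 * (dog[[li + 1L]][i, j + 1L] - dog[[li + 1L]][i, j - 1L] -
                         dog[[li - 1L]][i, j + 1L] + dog[[li - 1L]][i, j - 1L])
          dys <- 0.25 * (dog[[li + 1L]][i + 1L, j] - dog[[li + 1L]][i - 1L, j] -
                         dog[[li - 1L]][i + 1L, j] + dog[[li - 1L]][i - 1L, j])
          Hm <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3L, 3L)
          Hxy <- c(dxx, dyy, dxy)
          off <- tryCatch(solve(Hm, -dD), error = function(e) NULL)
          if (is.null(off) || any(!is.finite(off))) { off <- NULL; break }
          if (all(abs(off) < 0.5)) break
          j <- j + as.integer(round(off[1L]))
          i <- i + as.integer(round(off[2L]))
          li <- li + as.integer(round(off[3L]))
          if (li < 2L || li > s + 1L || i <= border || i > ho - border ||
              j <= border || j > wo - border) { off <- NULL; break }
          if (iter == 5L) off <- NULL
        }
        if (is.null(off) || any(abs(off) > 0.6)) next
        val <- dog[[li]][i, j] + 0.5 * sum(dD * off)
        if (abs(val) < peak_thr) next
        tr <- Hxy[1L] + Hxy[2L]
        det <- Hxy[1L] * Hxy[2L] - Hxy[3L]^2
        if (det <= 0 || tr^2 / det >= (edge_ratio + 1)^2 / edge_ratio) next
        sig_oct <- sigma0 * 2^((li - 1L + off[3L]) / s)
        gi <- min(max(as.integer(round(li + off[3L])), 1L), s + 3L)
        theta <- dominant_orientation(gauss, gi, i + off[2L], j + off[1L],
                                      sig_oct, grad_cache)
        if (is.na(theta)) next
        n_out <- n_out + 1L
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        out[[n_out]] <- c(x = unname((j - 1L + off[1L]) * 2^(o - 1L) * coord_mult),
                          y = unname((i - 1L + off[2L]) * 2^(o - 1L) * coord_mult),
                          scale = unname(sig_oct * 2^(o - 1L) * coord_mult),
                          orientation = unname(theta))
      }
    }
    if (o < n_oct) {
      nxt <- gauss[[s + 1L]]                 # sigma = 2 * sigma0
      base <- nxt[seq(1L, nrow(nxt), by = 2L), seq(1L, ncol(nxt), by = 2L),
                  drop = FALSE]
    }
  }

  if (n_out == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      scale = numeric(0), orientation = numeric(0)))
  kp <- as.data.frame(do.call(rbind, out[seq_len(n_out)]))
  # de-duplicate points that converged to the same location/scale
  key <- paste(round(kp$x, 2L), round(kp$y, 2L), round(kp$scale, 2L))
  kp <- kp[!duplicated(key), , drop = FALSE]
  kp <- kp[order(kp$y, kp$x, kp$scale), , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

# Dominant gradient orientation (radians in [0, 2*pi)) around a point in
# octave coordinates, from a 36-bin magnitude-weighted histogram smoothed
# circularly, with parabolic peak interpolation.
dominant_orientation <- function(gauss, gi, i, j, sig_oct, cache) {
  key <- as.character(gi)
  if (is.null(cache[[key]])) {
    gm <- gauss[[gi]]
    h <- nrow(gm); w <- ncol(gm)
    gx <- 0.5 * (gm[, c(2:w, w), drop = FALSE] - gm[, c(1L, 1:(w - 1L)), drop = FALSE])
    gy <- 0.5 * (gm[c(2:h, h), , drop = FALSE] - gm[c(1L, 1:(h - 1L)), , drop = FALSE])
    cache[[key]] <- list(mag = sqrt(gx^2 + gy^2),
                         ang = atan2(gy, gx) %% (2 * pi))
  }
  gr <- cache[[key]]
  h <- nrow(gr$mag); w <- ncol(gr$mag)
  sw <- 1.5 * sig_oct
  r <- max(2L, as.integer(round(3 * sw)))
  ri <- max(2L, as.integer(round(i)) - r):min(h - 1L, as.integer(round(i)) + r)
  ci <- max(2L, as.integer(round(j)) - r):min(w - 1L, as.integer(round(j)) + r)
  if (length(ri) < 1L || length(ci) < 1L) return(NA_real_)
  dy <- outer(ri - i, rep(1, length(ci)))
  dx <- outer(rep(1, length(ri)), ci - j)
  wgt <- exp(-(dx^2 + dy^2) / (2 * sw^2)) * gr$mag[ri, ci, drop = FALSE]
  bins <- pmin(as.integer(gr$ang[ri, ci, drop = FALSE] / (2 * pi) * 36) + 1L, 36L)
  hist <- numeric(36L)
  acc <- rowsum(as.vector(wgt), as.vector(bins))
  hist[as.integer(rownames(acc))] <- acc
  if (sum(hist) <= 0) return(NA_real_)
  for (pass in 1:6)
    hist <- (hist[c(36L, 1:35)] + hist + hist[c(2:36, 1L)]) / 3
  b <- which.max(hist)
  l <- hist[if (b == 1L) 36L else b - 1L]
  rgt <- hist[if (b == 36L) 1L else b + 1L]
  den <- l - 2 * hist[b] + rgt
  dlt <- if (abs(den) < 1e-12) 0 else 0.5 * (l - rgt) / den
  ((b - 1 + 0.5 + dlt) * (2 * pi / 36)) %% (2 * pi)
}
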