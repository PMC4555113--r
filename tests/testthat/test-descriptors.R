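textured_image <- function(seed = 5, n = 3) {
  generate_image(default_category_specs(n), seed = seed)$record
}

kp_df <- function(x, y, scale, orientation = 0) {
  data.frame(x = x, y = y, scale = scale, orientation = orientation)
}

test_that("shape descriptors are 128-dim, non-negative, unit norm", {
  img <- textured_image()
  pts <- detect_interest_points(img)
  expect_gt(nrow(pts), 5L)
  d <- shape_descriptors(img, pts)
  expect_equal(dim(d), c(nrow(pts), 128L))
  expect_true(all(d >= 0))
  expect_equal(sqrt(rowSums(d^2)), rep(1, nrow(pts)), tolerance = 1e-6)
  # empty point list -> empty descriptor matrix
  expect_equal(nrow(shape_descriptors(img, pts[0, ])), 0L)
  # point outside the image is rejected
  expect_error(shape_descriptors(img, kp_df(5000, 5, 2)), "outside")
})

test_that("shape descriptors are invariant to 90-degree rotation with a rotated keypoint", {
  img <- textured_image(seed = 9)
  pts <- detect_interest_points(img)
  pts <- pts[order(-pts$scale), ][1:min(5, nrow(pts)), ]
  h <- dim(img$pixels)[1]; w <- dim(img$pixels)[2]
  # rotate image 90 degrees counter-clockwise: (x, y) -> (y, W-1-x)
  rot <- image_record(aperm(img$pixels, c(2, 1, 3))[w:1, , , drop = FALSE])
  pts_rot <- kp_df(pts$y, w - 1 - pts$x, pts$scale,
                   (pts$orientation - pi / 2) %% (2 * pi))
  d0 <- shape_descriptors(img, pts)
  d1 <- shape_descriptors(rot, pts_rot)
  dist <- sqrt(rowSums((d0 - d1)^2))
  expect_true(all(dist < 0.15))
})

test_that("texture histograms are L1-normalized and flat patches hit the all-zeros pattern", {
  flat <- image_record(matrix(100, 64, 64))
  d <- texture_descriptors(flat, kp_df(32, 32, 2))
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(d[1, 1], 1)    # bin 1 = uniform pattern 00000000
  img <- textured_image(seed = 3)
  pts <- detect_interest_points(img)
  d <- texture_descriptors(img, pts)
  expect_equal(dim(d), c(nrow(pts), 59L))
  expect_true(all(d >= 0))
  expect_equal(rowSums(d), rep(1, nrow(pts)), tolerance = 1e-9)
})

test_that("texture histograms are invariant to monotone intensity shifts", {
  set.seed(11)
  base <- matrix(sample(20:200, 80 * 80, replace = TRUE), 80, 80)
  img <- image_record(base)
  img_shift <- image_record(pmin(base + 40, 255))   # stays below clipping
  pts <- kp_df(c(20, 40, 60), c(25, 45, 30), c(1.5, 2, 3))
  expect_equal(texture_descriptors(img, pts),
               texture_descriptors(img_shift, pts))
})

test_that("colour descriptors bin RGB into 4x4x4 with R-major layout", {
  red <- array(rep(c(255, 0, 0), each = 64 * 64), dim = c(64, 64, 3))
  d <- colour_descriptors(image_record(red), kp_df(32, 32, 2))
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_equal(d[1, 3 * 16 + 0 * 4 + 0 + 1], 1)   # R-bin 3, G-bin 0, B-bin 0
  # half pure red / half pure blue -> 0.5 in each of the two bins
  halfhalf <- red
  halfhalf[, 33:64, 1] <- 0
  halfhalf[, 33:64, 3] <- 255
  d <- colour_descriptors(image_record(halfhalf), kp_df(31.5, 32, 6))
  expect_equal(d[1, 3 * 16 + 1], 0.5, tolerance = 0.02)
  expect_equal(d[1, 0 * 16 + 0 * 4 + 3 + 1], 0.5, tolerance = 0.02)
  img <- textured_image(seed = 21)
  pts <- detect_interest_points(img)
  d <- colour_descriptors(img, pts)
  expect_true(all(d >= 0))
  expect_equal(rowSums(d), rep(1, nrow(pts)), tolerance = 1e-9)
})

test_that("the global colour histogram matches hand-binned values and is additive", {
  black <- image_record(array(0, dim = c(4, 4, 3)))
  h <- colour_histogram_global(black)
  expect_equal(h[1], 1)
  # four grey pixels, one per quantization bin
  px <- array(rep(c(0, 80, 160, 240), 3), dim = c(2, 2, 3))
  h <- colour_histogram_global(image_record(px))
  expect_equal(h[0 * 21 + 1], 0.25)   # (0,0,0)
  expect_equal(h[1 * 21 + 1], 0.25)   # (1,1,1)
  expect_equal(h[2 * 21 + 1], 0.25)   # (2,2,2)
  expect_equal(h[3 * 21 + 1], 0.25)   # (3,3,3)
  # additivity: whole-image histogram = pixel-weighted mix of tile histograms
  img <- textured_image(seed = 13)$pixels
  top <- image_record(img[1:64, , , drop = FALSE])
  bot <- image_record(img[65:128, , , drop = FALSE])
  expect_equal(colour_histogram_global(image_record(img)),
               0.5 * colour_histogram_global(top) +
                 0.5 * colour_histogram_global(bot),
               tolerance = 1e-12)
})

test_that("feature extraction is deterministic and index-aligned across channels", {
  img <- textured_image(seed = 29)
  f1 <- extract_features(img)
  f2 <- extract_features(img)
  expect_identical(f1, f2)
  n <- nrow(f1$points)
  expect_equal(nrow(f1$shape), n)
  expect_equal(nrow(f1$texture), n)
  expect_equal(nrow(f1$colour), n)
})
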