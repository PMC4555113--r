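test_that("a smooth zero-jitter disc renders as uniform base colour", {
  spec <- category_spec("probe", c(200, 50, 100), jitter = 0,
                        texture = "smooth", shape = "disc", size = c(15, 15))
  canvas <- array(128, dim = c(96, 96, 3))
  set.seed(1)
  out <- render_item(canvas, spec, position = c(48, 48), size = 15)
  # interior pixels (inside the anti-aliased rim) equal the base colour
  xs <- matrix(rep(1:96 - 48, each = 96), 96)
  ys <- matrix(rep(1:96 - 48, times = 96), 96)
  interior <- sqrt(xs^2 + ys^2) <= 13
  for (ch in 1:3)
    expect_true(all(out[, , ch][interior] == spec$colour[ch]))
  # pixels far outside are untouched
  expect_true(all(out[, , 1][sqrt(xs^2 + ys^2) > 17] == 128))
  expect_error(render_item(canvas, spec, position = c(200, 48)), "outside")
  expect_error(render_item(canvas, spec, position = c(48, 48), size = 90),
               "larger than canvas")
})

test_that("stripe texture has its dominant period at the requested frequency", {
  spec <- category_spec("striped", c(180, 180, 180), jitter = 0,
                        texture = "stripe", frequency = 8, contrast = 0.5,
                        shape = "disc", size = c(30, 30))
  canvas <- array(128, dim = c(96, 96, 3))
  set.seed(2)
  out <- render_item(canvas, spec, position = c(48, 48), size = 30)
  profile <- out[48, 20:76, 1]           # horizontal line through the centre
  spec_pow <- Mod(fft(profile - mean(profile)))^2
  n <- length(profile)
  freqs <- seq_len(n %/% 2)              # cycles over the window
  peak <- freqs[which.max(spec_pow[freqs + 1])]
  period <- n / peak
  expect_gte(period, 7)
  expect_lte(period, 9)
})

test_that("rendering and image generation are deterministic under a seed", {
  specs <- default_category_specs(3)
  g1 <- generate_image(specs, seed = 40)
  g2 <- generate_image(specs, seed = 40)
  expect_identical(g1$record$pixels, g2$record$pixels)
  expect_setequal(g1$labels, vapply(specs, `[[`, character(1), "name"))
  # five distinct specs -> label set of size 5
  g5 <- generate_image(default_category_specs(5), seed = 41)
  expect_length(g5$labels, 5L)
  expect_error(generate_image(default_category_specs(6), seed = 1), "1..5")
})

test_that("rendered items have mean colour near their spec's base colour", {
  spec <- category_spec("probe", c(60, 180, 220), jitter = 6,
                        texture = "speckle", frequency = 4, contrast = 0.3,
                        shape = "disc", size = c(20, 20))
  set.seed(3)
  canvas <- array(128, dim = c(96, 96, 3))
  out <- render_item(canvas, spec, position = c(48, 48), size = 20)
  xs <- matrix(rep(1:96 - 48, each = 96), 96)
  ys <- matrix(rep(1:96 - 48, times = 96), 96)
  interior <- sqrt(xs^2 + ys^2) <= 16
  for (ch in 1:3)
    expect_lt(abs(mean(out[, , ch][interior]) - spec$colour[ch]),
              0.2 * spec$colour[ch] + 15)
})

test_that("dataset generation writes the expected rows and is byte-reproducible", {
  d1 <- withr::local_tempdir()
  man <- generate_dataset(d1, n_categories = 2, train_per_category = 3,
                          test_per_category = 5, multi_label_fraction = 0,
                          seed = 9, specs = default_category_specs(2))
  expect_equal(sum(man$split == "train"), 6L)
  expect_equal(sum(man$split == "test"), 10L)
  expect_true(all(!grepl(";", man$labels[man$split == "test"])))
  expect_true(all(file.exists(man$abs_path)))
  # exact multi-label counts
  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(d2, n_categories = 4, train_per_category = 2,
                           test_per_category = 5, multi_label_fraction = 0.5,
                           seed = 9, specs = default_category_specs(4))
  test2 <- man2[man2$split == "test", ]
  expect_equal(nrow(test2), 20L)
  expect_equal(sum(grepl(";", test2$labels)), 10L)
  # byte-identical regeneration from the same seed
  d3 <- withr::local_tempdir()
  man3 <- generate_dataset(d3, n_categories = 2, train_per_category = 3,
                           test_per_category = 5, multi_label_fraction = 0,
                           seed = 9, specs = default_category_specs(2))
  expect_equal(man[, c("image_path", "labels", "split")],
               man3[, c("image_path", "labels", "split")])
  for (i in seq_len(nrow(man)))
    expect_identical(readBin(man$abs_path[i], "raw", file.size(man$abs_path[i])),
                     readBin(man3$abs_path[i], "raw", file.size(man3$abs_path[i])))
})
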