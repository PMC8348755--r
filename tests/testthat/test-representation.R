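test_that("matrix images map one cell to one pixel through the colormap", {
  set.seed(2)
  r <- eeg_record(matrix(rnorm(23 * 256), 23), fs = 128)
  fm <- fft_band_features(r, c(1, 23))
  img <- render_matrix_image(fm, label = "seizure")
  expect_s3_class(img, "representation_image")
  expect_equal(dim(img$pixels), c(23L, 23L, 3L))
  expect_equal(img$label, "seizure")
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
})

test_that("matrix rendering is invariant to affine rescaling of the map", {
  set.seed(3)
  fm1 <- feature_map(matrix(runif(12), 3), "channel", "frequency",
                     1:3, 1:4)
  fm2 <- feature_map(fm1$values * 7 + 100, "channel", "frequency",
                     1:3, 1:4)
  expect_equal(render_matrix_image(fm1)$pixels,
               render_matrix_image(fm2)$pixels)
})

test_that("a constant feature map renders as a uniform image", {
  fm <- feature_map(matrix(5, 4, 6), "channel", "frequency", 1:4, 1:6)
  img <- render_matrix_image(fm)
  for (ch in 1:3) expect_length(unique(as.numeric(img$pixels[, , ch])), 1L)
})

test_that("scalogram images are resized to the target resolution and banded", {
  fs <- 64
  tt <- (0:255) / fs
  r <- eeg_record(matrix(sin(2 * pi * 8 * tt), 1), fs = fs)
  fm <- cwt_scalogram(r, total_scale = 10L)
  img <- render_scalogram_image(fm, out_res = 48L, levels = 10L)
  expect_equal(dim(img$pixels), c(48L, 48L, 3L))
  # discretization into at most `levels` contour bands
  n_colors <- nrow(unique(matrix(img$pixels, ncol = 3L)))
  expect_lte(n_colors, 10L)
})

test_that("scale 1 sits at the bottom row of the rendered scalogram", {
  # map with all energy at the smallest scale (row 1)
  vals <- matrix(0, 10, 32); vals[1, ] <- 1
  fm <- feature_map(vals, "scale", "time", 1:10, 1:32)
  img <- render_scalogram_image(fm, out_res = 20L, levels = 2L)
  expect_false(isTRUE(all.equal(img$pixels[20, 1, ], img$pixels[1, 1, ])))
  # the bright band must be at the bottom (high row index in image space)
  bright <- which.max(rowSums(img$pixels[, , 1]))
  expect_gt(bright, 10L)
})

test_that("augmentation returns the original plus one image per operation", {
  set.seed(5)
  img <- render_matrix_image(feature_map(matrix(runif(20), 4), "channel",
                                         "frequency", 1:4, 1:5))
  out <- augment(img, c("flip_h", "rot90"))
  expect_length(out, 3L)
  expect_equal(out[[1]]$pixels, img$pixels)
  expect_equal(dim(out[[3]]$pixels)[1:2], dim(img$pixels)[2:1])
  expect_error(augment(img, "sharpen"), class = "seiznet_validation_error")
})

test_that("flips and rotations are involutions / 4-cycles", {
  set.seed(6)
  img <- render_matrix_image(feature_map(matrix(runif(30), 5), "channel",
                                         "frequency", 1:5, 1:6))
  fh <- augment(img, "flip_h")[[2]]
  expect_equal(augment(fh, "flip_h")[[2]]$pixels, img$pixels)
  r <- img
  for (i in 1:4) r <- augment(r, "rot90")[[2]]
  expect_equal(r$pixels, img$pixels)
  expect_equal(augment(img, "rot180")[[2]]$pixels,
               augment(augment(img, "rot90")[[2]], "rot90")[[2]]$pixels)
})

test_that("bilinear resize is the identity at the native size", {
  m <- matrix(rnorm(64), 8)
  expect_equal(resize_bilinear_matrix(m, 8, 8), m)
})

test_that("network inputs are normalized channels-first tensors", {
  set.seed(7)
  img <- render_matrix_image(feature_map(matrix(runif(23 * 23), 23),
                                         "channel", "frequency", 1:23, 1:23),
                             label = "seizure")
  inp <- to_net_input(img, 64L)
  expect_s3_class(inp, "net_input")
  expect_equal(dim(inp$tensor), c(3L, 64L, 64L))
  expect_equal(inp$label, "seizure")
  # undo the normalization: intensities must return to [0, 1]
  norm <- imagenet_norm()
  for (ch in 1:3) {
    plane <- inp$tensor[ch, , ] * norm$sd[ch] + norm$mean[ch]
    expect_gte(min(plane), -1e-9)
    expect_lte(max(plane), 1 + 1e-9)
  }
})

test_that("representation images round trip through PNG with sidecar", {
  set.seed(8)
  img <- render_matrix_image(feature_map(matrix(runif(20), 4), "channel",
                                         "frequency", 1:4, 1:5),
                             label = "seizure")
  path <- tempfile(fileext = ".png")
  write_representation_image(img, path)
  px <- png::readPNG(path) * 255
  expect_equal(px, img$pixels, tolerance = 0.51)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$label, "seizure")
})
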