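# Direct (quadratic-time) discrete Fourier magnitude oracle.
naive_band_features <- function(slice, band, spacing = 1) {
  x <- slice$data
  n <- ncol(x)
  fs <- slice$fs
  freqs <- seq(band[1], band[2], by = spacing)
  out <- matrix(0, nrow(x), length(freqs))
  bin_f <- (seq_len(n) - 1) * fs / n
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ] - mean(x[ch, ])
    mag <- vapply(seq_len(n), function(k) {
      Mod(sum(v * exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n)))
    }, 0)
    for (j in seq_along(freqs)) {
      sel <- bin_f >= freqs[j] - spacing / 2 & bin_f < freqs[j] + spacing / 2
      out[ch, j] <- mean(mag[sel])
    }
  }
  out
}

test_that("the wavelet center frequency matches its spectral peak", {
  fc <- wavelet_center_frequency("cgau8")
  expect_equal(fc, (1 + sqrt(1 + 8 * 8)) / (4 * pi), tolerance = 1e-12)
  # numerical spectral peak of the sampled mother wavelet; the complex
  # carrier exp(-it) puts the peak on the negative-frequency side, so
  # compare the magnitude of the two-sided peak location
  dt <- 1 / 64
  tt <- seq(-8, 8, by = dt)
  psi <- seiznet:::cgau_wavelet(tt)
  n_pad <- 2^16
  spec <- Mod(stats::fft(c(psi, rep(0, n_pad - length(psi)))))
  f <- (seq_len(n_pad) - 1) / (n_pad * dt)
  f[f >= 1 / (2 * dt)] <- f[f >= 1 / (2 * dt)] - 1 / dt
  expect_equal(abs(f[which.max(spec)]), fc, tolerance = 2e-3)
})

test_that("the mother wavelet has unit L2 norm", {
  tt <- seq(-8, 8, length.out = 2^14)
  psi <- seiznet:::cgau_wavelet(tt)
  expect_equal(sum(Mod(psi)^2) * diff(tt[1:2]), 1, tolerance = 1e-6)
})

test_that("scalograms have scale-by-time geometry and peak at the tone scale", {
  fs <- 64
  f0 <- 8
  tt <- (0:511) / fs
  r <- eeg_record(matrix(sin(2 * pi * f0 * tt), 1), fs = fs)
  fm <- cwt_scalogram(r, total_scale = 10L)
  expect_s3_class(fm, "feature_map")
  expect_equal(dim(fm$values), c(10L, 512L))
  expect_equal(fm$row_axis, "scale")
  # energy concentrates at the scale mapping to f0: a = fc * fs / f0
  a_star <- wavelet_center_frequency("cgau8") * fs / f0
  energy <- rowMeans(fm$values^2)
  expect_equal(which.max(energy), round(a_star))
})

test_that("the scalogram rejects multichannel slices and points to the spectral path", {
  r <- eeg_record(matrix(rnorm(256), 2), fs = 64)
  err <- expect_error(cwt_scalogram(r), class = "seiznet_validation_error")
  expect_match(conditionMessage(err), "fft_band_features")
})

test_that("spectral band features match a naive DFT oracle", {
  set.seed(4)
  r <- eeg_record(matrix(rnorm(3 * 256), 3), fs = 64)
  fm <- fft_band_features(r, c(1, 16), spacing = 1)
  expect_equal(dim(fm$values), c(3L, 16L))
  oracle <- naive_band_features(slice_record(r, window_config(4, 0))[[1]],
                                c(1, 16))
  expect_equal(fm$values, oracle, tolerance = 1e-10)
})

test_that("a pure tone concentrates its band feature at the tone frequency", {
  fs <- 128
  tt <- (0:255) / fs
  r <- eeg_record(matrix(sin(2 * pi * 10 * tt), 1), fs = fs)
  fm <- fft_band_features(r, c(1, 23))
  expect_equal(fm$col_labels[which.max(fm$values[1, ])], 10)
})

test_that("band feature preconditions are enforced with helpful errors", {
  r <- eeg_record(matrix(rnorm(2 * 128), 2), fs = 64)
  expect_error(fft_band_features(r, c(1, 40)),
               class = "seiznet_validation_error")  # above Nyquist
  expect_error(fft_band_features(r, c(16, 1)),
               class = "seiznet_validation_error")  # reversed band
  short <- eeg_record(matrix(rnorm(2 * 32), 2), fs = 64)  # 0.5 s
  err <- expect_error(fft_band_features(short, c(1, 16), spacing = 1),
                      class = "seiznet_validation_error")
  expect_match(conditionMessage(err), "1")
})

test_that("feature maps round trip through the columnar on-disk format", {
  r <- eeg_record(matrix(rnorm(2 * 128), 2), fs = 64)
  fm <- fft_band_features(r, c(1, 16))
  path <- tempfile(fileext = ".tsv")
  write_feature_map(fm, path)
  fm2 <- read_feature_map(path)
  expect_equal(fm2$values, fm$values, tolerance = 1e-12)
  expect_equal(fm2$row_axis, fm$row_axis)
  expect_equal(fm2$col_labels, fm$col_labels)
})

test_that("feature maps reject non-finite values", {
  expect_error(feature_map(matrix(c(1, NA, 2, 3), 2), "scale", "time",
                           1:2, 1:2),
               class = "seiznet_validation_error")
})
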