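# Spectral feature extraction from EEG slices: continuous wavelet
# transform scalograms for single-channel slices, per-channel Fourier
# band magnitudes for multichannel slices.

#' 2D feature map
#'
#' A real-valued matrix with named axes: scale x time (scalogram) or
#' channel x frequency (Fourier band matrix).
#'
#' @param values numeric matrix, all entries finite.
#' @param row_axis `"scale"` or `"channel"`.
#' @param col_axis `"time"` or `"frequency"`.
#' @param row_labels,col_labels axis labels (scales / channel names, and
#'   seconds / Hz); lengths must match `dim(values)`.
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(values, row_axis = c("scale", "channel"),
                        col_axis = c("time", "frequency"),
                        row_labels = NULL, col_labels = NULL) {
  row_axis <- match.arg(row_axis)
  col_axis <- match.arg(col_axis)
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(is.finite(values))) {
    stop_seiznet("feature map values must all be finite",
                 "seiznet_validation_error")
  }
  row_labels <- row_labels %||% seq_len(nrow(values))
  col_labels <- col_labels %||% seq_len(ncol(values))
  if (length(row_labels) != nrow(values) || length(col_labels) != ncol(values)) {
    stop_seiznet("axis label lengths must match the value matrix",
                 "seiznet_validation_error")
  }
  structure(list(values = values, row_axis = row_axis, col_axis = col_axis,
                 row_labels = row_labels, col_labels = col_labels),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %d %s x %d %s\n", nrow(x$values), x$row_axis,
              ncol(x$values), x$col_axis))
  invisible(x)
}

# --- complex Gaussian wavelet --------------------------------------------

# The order-n complex Gaussian wavelet is the nth derivative of
# f(t) = exp(-i t) exp(-t^2), L2-normalized. Differentiating f repeatedly
# leaves a polynomial factor: p_0 = 1, p_{k+1}(t) = p_k'(t) + (-i - 2t) p_k(t).
cgau_poly <- function(order) {
  p <- c(1 + 0i)  # ascending powers
  for (k in seq_len(order)) {
    deg <- length(p) - 1L
    dp <- if (deg >= 1L) p[-1L] * seq_len(deg) else 0 + 0i
    a <- c(dp, 0 + 0i, 0 + 0i)[seq_len(deg + 2L)]
    b <- c(-1i * p, 0 + 0i) + c(0 + 0i, -2 * p)
    p <- a + b
  }
  p
}

cgau_env <- new.env(parent = emptyenv())

# Evaluate the L2-normalized order-`order` complex Gaussian wavelet at t.
# The normalization constant is computed once per order on a fine grid
# over the effective support [-8, 8] and cached.
cgau_wavelet <- function(t, order = 8L) {
  key <- as.character(order)
  if (is.null(cgau_env[[key]])) {
    p <- cgau_poly(order)
    tt <- seq(-8, 8, length.out = 2^14)
    raw <- polyval_c(p, tt) * exp(-1i * tt - tt^2)
    nrm <- sqrt(sum(Mod(raw)^2) * (tt[2] - tt[1]))
    cgau_env[[key]] <- list(poly = p, norm = nrm)
  }
  w <- cgau_env[[key]]
  polyval_c(w$poly, t) * exp(-1i * t - t^2) / w$norm
}

# Horner evaluation of a complex polynomial given ascending coefficients.
polyval_c <- function(p, t) {
  out <- rep(p[length(p)], length(t))
  for (k in rev(seq_len(length(p) - 1L))) out <- out * t + p[k]
  out
}

#' Center frequency of the analysis wavelet
#'
#' The dominant frequency (in cycles per unit time) of the order-n complex
#' Gaussian wavelet. Its spectrum is proportional to
#' `|w|^n exp(-(w + 1)^2 / 4)` (angular frequency `w`), whose modulus
#' peaks where `w^2 + w - 2n = 0`, so
#' `fc = (1 + sqrt(1 + 8 n)) / (4 pi)` cycles per unit time
#' (about 0.721 for order 8). Scale `a` at sampling rate `fs` then
#' analyzes frequency `fc * fs / a` Hz.
#'
#' @param wavelet wavelet name; `"cgau8"` (order-8 complex Gaussian) or
#'   `"cgauN"` for order N.
#' @return center frequency in cycles per unit of the wavelet's time axis.
#' @export
wavelet_center_frequency <- function(wavelet = "cgau8") {
  order <- parse_cgau_order(wavelet)
  (1 + sqrt(1 + 8 * order)) / (4 * pi)
}

parse_cgau_order <- function(wavelet) {
  m <- regmatches(wavelet, regexec("^cgau([1-9][0-9]*)$", wavelet))[[1]]
  if (length(m) != 2L) {
    stop_seiznet(sprintf(
      "unsupported wavelet '%s'; complex Gaussian wavelets ('cgau1'..'cgau8', ...) are available",
      wavelet), "seiznet_validation_error")
  }
  as.integer(m[2])
}

#' Scales targeting given analysis frequencies
#'
#' The inverse of the scale-to-frequency map `f = fc * fs / a`: returns
#' the CWT scales at which the wavelet's center frequency lands on each
#' requested frequency. An alternative to plain integer scales
#' `1..total_scale` when specific bands are of interest.
#'
#' @param freqs_hz target frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param wavelet wavelet name.
#' @return numeric vector of scales.
#' @export
cwt_scales_for_frequencies <- function(freqs_hz, fs, wavelet = "cgau8") {
  stopifnot(all(freqs_hz > 0), fs > 0)
  wavelet_center_frequency(wavelet) * fs / freqs_hz
}

#' Continuous wavelet transform scalogram of a single-channel slice
#'
#' Computes `|W(a, b)|` where
#' `W(a, b) = a^(-1/2) * sum_n x[n] conj(psi((n - b) / a))`,
#' at scales `a = 1 .. total_scale` (or an explicit `scales` vector), with
#' the order-8 complex Gaussian mother wavelet by default. The convolution
#' is evaluated in the frequency domain with zero padding; the wavelet is
#' sampled over its effective support `[-8a, 8a]`.
#'
#' @param slice a single-channel `eeg_slice` (or [eeg_record()]).
#' @param wavelet wavelet name, default `"cgau8"`.
#' @param total_scale number of integer scales, `>= 1`.
#' @param scales optional explicit scale vector overriding `1:total_scale`
#'   (e.g. from [cwt_scales_for_frequencies()]).
#' @return a [feature_map()] of shape `(length(scales), window_samples)`,
#'   rows labeled by scale, columns by time in seconds.
#' @export
cwt_scalogram <- function(slice, wavelet = "cgau8", total_scale = 10L,
                          scales = NULL) {
  x <- slice_signal(slice)
  if (nrow(x$data) != 1L) {
    stop_seiznet(paste0(
      "cwt_scalogram expects a single-channel slice (got ", nrow(x$data),
      " channels); use fft_band_features for multichannel slices"),
      "seiznet_validation_error")
  }
  order <- parse_cgau_order(wavelet)
  if (is.null(scales)) {
    stopifnot(total_scale >= 1L)
    scales <- seq_len(total_scale)
  }
  stopifnot(all(scales > 0))
  sig <- as.vector(x$data)
  n <- length(sig)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    half <- ceiling(8 * a)
    k <- (-half):half
    kern <- Conj(cgau_wavelet(k / a, order)) / sqrt(a)
    # W[b] = sum_k x[b + k] kern[k]: cross-correlation, zero-padded FFT
    m <- stats::nextn(n + length(kern) - 1L, 2L)
    xp <- c(sig, rep(0, m - n))
    kp <- c(rev(kern), rep(0, m - length(kern)))
    full <- stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE) / m
    out[i, ] <- Mod(full[(half + 1L):(half + n)])
  }
  feature_map(out, row_axis = "scale", col_axis = "time",
              row_labels = scales,
              col_labels = x$t_start_s + (seq_len(n) - 1) / x$fs)
}

# Accept either an eeg_slice or an eeg_record where a slice is expected.
slice_signal <- function(slice) {
  if (inherits(slice, "eeg_slice")) return(slice)
  if (inherits(slice, "eeg_record")) {
    return(new_eeg_slice(slice$data, slice$fs, 0, "nonseizure",
                         slice$subject_id, slice$record_id))
  }
  stop_seiznet("expected an eeg_slice or eeg_record",
               "seiznet_validation_error")
}

#' Per-channel Fourier magnitude features over a frequency band
#'
#' For each channel, removes the channel mean, takes the discrete Fourier
#' transform, and averages the magnitude over bins falling in
#' `[f - spacing/2, f + spacing/2)` for each center frequency
#' `f = lo, lo + spacing, ..., hi`. A 23-channel slice with band
#' `(1, 23)` Hz at 1 Hz spacing yields a 23 x 23 matrix; extending the
#' band to `(1, 46)` Hz yields 23 x 46.
#'
#' @param slice an `eeg_slice` (or [eeg_record()]), any channel count.
#' @param band numeric length-2 `(lo, hi)` in Hz with
#'   `spacing <= lo <= hi < fs/2`.
#' @param spacing center-frequency spacing in Hz, default 1.
#' @return a [feature_map()] of shape `(channels, n_centers)`, rows labeled
#'   by channel name, columns by center frequency in Hz.
#' @export
fft_band_features <- function(slice, band, spacing = 1) {
  x <- slice_signal(slice)
  stopifnot(length(band) == 2L, spacing > 0)
  lo <- band[1]; hi <- band[2]
  if (!(hi >= lo && lo >= spacing)) {
    stop_seiznet("band must satisfy spacing <= lo <= hi",
                 "seiznet_validation_error")
  }
  if (hi >= x$fs / 2) {
    stop_seiznet(sprintf("band upper edge (%g Hz) must lie below Nyquist (%g Hz)",
                         hi, x$fs / 2), "seiznet_validation_error")
  }
  n <- ncol(x$data)
  bin_freqs <- (seq_len(n) - 1) * x$fs / n
  centers <- seq(lo, hi, by = spacing)
  if (x$fs / n > spacing) {
    stop_seiznet(sprintf(
      "window too short for %g Hz spacing: DFT bin width %g Hz leaves empty aggregation bins; minimum window length is %g s",
      spacing, x$fs / n, 1 / spacing), "seiznet_validation_error")
  }
  vals <- matrix(0, nrow = nrow(x$data), ncol = length(centers))
  for (ch in seq_len(nrow(x$data))) {
    sig <- x$data[ch, ] - mean(x$data[ch, ])
    mags <- Mod(stats::fft(sig))
    for (j in seq_along(centers)) {
      sel <- bin_freqs >= centers[j] - spacing / 2 &
        bin_freqs < centers[j] + spacing / 2
      if (!any(sel)) {
        stop_seiznet(sprintf(
          "empty aggregation bin at %g Hz; minimum window length is %g s",
          centers[j], 1 / spacing), "seiznet_validation_error")
      }
      vals[ch, j] <- mean(mags[sel])
    }
  }
  ch_names <- rownames(x$data) %||% paste0("ch", seq_len(nrow(x$data)))
  feature_map(vals, row_axis = "channel", col_axis = "frequency",
              row_labels = ch_names, col_labels = centers)
}

#' Write a feature map to disk
#'
#' Values go to a tab-separated text file; axis metadata to a JSON sidecar
#' at `<path>.json`.
#'
#' @param fm a [feature_map()].
#' @param path output path for the TSV matrix.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fm, path) {
  stopifnot(inherits(fm, "feature_map"))
  utils::write.table(fm$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(row_axis = fm$row_axis, col_axis = fm$col_axis,
         row_labels = fm$row_labels, col_labels = fm$col_labels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature map written by [write_feature_map()]
#' @param path path to the TSV matrix (sidecar expected at `<path>.json`).
#' @return a [feature_map()].
#' @export
read_feature_map <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_map(vals, row_axis = meta$row_axis, col_axis = meta$col_axis,
              row_labels = meta$row_labels, col_labels = meta$col_labels)
}
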