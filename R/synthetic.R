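# Seeded synthetic EEG generator. Emulates the two signal classes the
# detection pipeline must separate: stationary 1/f-like background
# activity (interictal) and the same background plus a high-amplitude
# rhythmic oscillation confined to a frequency band (ictal). Used as a
# download-free stand-in for public EEG archives in tests and experiments.

#' Specification of a synthetic EEG corpus
#'
#' Collects every parameter of the synthetic generator. Defaults describe
#' a small multichannel scalp-EEG-like corpus with an alpha-band (8-12 Hz)
#' ictal rhythm whose RMS is four times the background RMS - a strongly
#' separable regime in band power, which is exactly the property the
#' spectral front end of the pipeline detects.
#'
#' @param n_subjects number of synthetic subjects.
#' @param records_per_subject records per subject *per state*.
#' @param channels channels per record.
#' @param fs sampling rate, Hz.
#' @param duration_s record duration, seconds.
#' @param ictal_band numeric length-2, (lo, hi) Hz of the ictal rhythm;
#'   requires `lo < hi < fs/2`.
#' @param ictal_amplitude_ratio total RMS of an ictal record divided by the
#'   RMS of its background, `>= 0`. Since the oscillation adds power on top
#'   of the background, its RMS is `sqrt(ratio^2 - 1)` times the background
#'   RMS; any ratio `<= 1` degenerates to pure background (ictal records
#'   statistically indistinguishable from interictal ones).
#' @param noise_exponent spectral slope of the background: power density
#'   proportional to `f^(-noise_exponent)`. `1` gives pink noise.
#' @param seed base seed; every record derives its own independent stream
#'   from `(seed, subject, record, state)`, so enlarging the corpus never
#'   perturbs existing records.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 4L, records_per_subject = 4L,
                           channels = 1L, fs = 173.61, duration_s = 23.6,
                           ictal_band = c(8, 12), ictal_amplitude_ratio = 4,
                           noise_exponent = 1, seed = 1L) {
  stopifnot(n_subjects >= 1L, records_per_subject >= 1L, channels >= 1L,
            fs > 0, duration_s > 0, length(ictal_band) == 2L,
            ictal_amplitude_ratio >= 0)
  if (!(ictal_band[1] < ictal_band[2])) {
    stop_seiznet("ictal_band must satisfy lo < hi", "seiznet_validation_error")
  }
  if (ictal_band[2] >= fs / 2) {
    stop_seiznet(sprintf(
      "ictal_band upper edge (%g Hz) must lie below the Nyquist frequency (%g Hz)",
      ictal_band[2], fs / 2), "seiznet_aliasing_error")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    records_per_subject = as.integer(records_per_subject),
    channels = as.integer(channels), fs = fs, duration_s = duration_s,
    ictal_band = as.numeric(ictal_band),
    ictal_amplitude_ratio = ictal_amplitude_ratio,
    noise_exponent = noise_exponent, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Colored Gaussian noise with power density ~ f^(-exponent), unit RMS.
# Shaped in the frequency domain: white spectrum scaled by f^(-exponent/2).
colored_noise <- function(n, fs, exponent) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)          # two-sided frequency axis
  shape <- c(0, freqs[-1]^(-exponent / 2))  # suppress DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG record
#'
#' Deterministic given `(spec$seed, state, subject, record)`. Interictal
#' records are colored noise with power density proportional to
#' `f^(-noise_exponent)`. Ictal records add, on every channel, a rhythmic
#' oscillation at a single dominant frequency drawn uniformly from
#' `ictal_band` (one draw per record), with 20% sinusoidal amplitude
#' modulation at 0.5 Hz, scaled so the record's total RMS equals
#' `ictal_amplitude_ratio` times the background RMS (oscillation RMS
#' `sqrt(ratio^2 - 1)` times background; none when `ratio <= 1`). Ictal
#' records carry a
#' single seizure annotation spanning the whole record.
#'
#' @param spec a [synthetic_spec()].
#' @param state `"ictal"` or `"interictal"`.
#' @param subject,record 1-based indices selecting the record's RNG stream.
#' @return an [eeg_record()].
#' @export
generate_synthetic <- function(spec, state = c("interictal", "ictal"),
                               subject = 1L, record = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  state <- match.arg(state)
  if (spec$ictal_band[2] >= spec$fs / 2) {
    stop_seiznet("ictal_band upper edge at or above Nyquist",
                 "seiznet_aliasing_error")
  }
  n <- floor(spec$duration_s * spec$fs)
  state_code <- if (state == "ictal") 2L else 1L
  stream <- mix_seed(spec$seed, subject, record, state_code)
  data <- with_seed(stream, {
    bg <- t(vapply(seq_len(spec$channels),
                   function(ch) colored_noise(n, spec$fs, spec$noise_exponent),
                   numeric(n)))
    if (state == "ictal") {
      f0 <- stats::runif(1, spec$ictal_band[1], spec$ictal_band[2])
      phase <- stats::runif(spec$channels, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / spec$fs
      am <- 1 + 0.2 * sin(2 * pi * 0.5 * tt)
      osc_gain <- sqrt(max(spec$ictal_amplitude_ratio^2 - 1, 0))
      for (ch in seq_len(spec$channels)) {
        osc <- am * sin(2 * pi * f0 * tt + phase[ch])
        if (osc_gain > 0) {
          osc <- osc / sqrt(mean(osc^2)) * osc_gain * sqrt(mean(bg[ch, ]^2))
          bg[ch, ] <- bg[ch, ] + osc
        }
      }
    }
    bg
  })
  ann <- if (state == "ictal") {
    list(seizure_interval(0, n / spec$fs))
  } else {
    list()
  }
  eeg_record(data, fs = spec$fs,
             annotations = ann,
             subject_id = sprintf("S%02d", subject),
             record_id = sprintf("R%02d_%s", record, state))
}

#' Generate a full synthetic corpus
#'
#' Generates `records_per_subject` ictal and `records_per_subject`
#' interictal records for each of `n_subjects` subjects.
#'
#' @param spec a [synthetic_spec()].
#' @param states character vector of states to generate.
#' @return a list of [eeg_record()] objects.
#' @export
generate_synthetic_dataset <- function(spec,
                                       states = c("ictal", "interictal")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (r in seq_len(spec$records_per_subject)) {
      for (st in states) {
        out[[length(out) + 1L]] <- generate_synthetic(spec, st, s, r)
      }
    }
  }
  out
}
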