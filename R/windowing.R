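# Sliding-window decomposition of EEG records into labeled slices.

#' Sliding time-window configuration
#'
#' @param window_s window length in seconds, `> 0`.
#' @param overlap_frac fractional overlap between consecutive windows, in
#'   `[0, 1)`. `0.5` (50% overlap) doubles the slice count relative to
#'   disjoint windows.
#' @return an object of class `window_config` with the derived step
#'   `step_s = window_s * (1 - overlap_frac)`.
#' @export
window_config <- function(window_s, overlap_frac = 0.5) {
  stopifnot(is_scalar_number(window_s), is_scalar_number(overlap_frac))
  if (window_s <= 0) {
    stop_seiznet("window_s must be positive", "seiznet_validation_error")
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop_seiznet("overlap_frac must lie in [0, 1)", "seiznet_validation_error")
  }
  structure(list(window_s = window_s, overlap_frac = overlap_frac,
                 step_s = window_s * (1 - overlap_frac)),
            class = "window_config")
}

new_eeg_slice <- function(data, fs, t_start_s, label, subject_id, record_id) {
  structure(list(data = data, fs = fs, t_start_s = t_start_s, label = label,
                 subject_id = subject_id, record_id = record_id),
            class = "eeg_slice")
}

#' @export
print.eeg_slice <- function(x, ...) {
  cat(sprintf("<eeg_slice> %s/%s @ %.3f s: %d ch x %d samples, label=%s\n",
              x$subject_id, x$record_id, x$t_start_s, nrow(x$data),
              ncol(x$data), x$label))
  invisible(x)
}

# Merge possibly-overlapping intervals, return matrix with start/end cols.
merge_intervals <- function(annotations) {
  if (length(annotations) == 0L) return(matrix(numeric(0), ncol = 2L))
  m <- cbind(vapply(annotations, `[[`, 0, "start_s"),
             vapply(annotations, `[[`, 0, "end_s"))
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

#' Decompose an EEG record into labeled slices
#'
#' Slides a window of `cfg$window_s` seconds across the record in steps of
#' `cfg$step_s`; slice `k` (0-based) starts at `k * step_s`. A slice is
#' labeled `"seizure"` when the fraction of its extent covered by the
#' union of the record's seizure intervals is at least `label_rule`;
#' otherwise `"nonseizure"`. The default `label_rule = 1` keeps only
#' wholly-ictal slices on the seizure side, avoiding ambiguous boundary
#' windows.
#'
#' @param record an [eeg_record()].
#' @param cfg a [window_config()].
#' @param label_rule seizure-coverage threshold in `[0, 1]`.
#' @return a list of `eeg_slice` objects.
#' @export
slice_record <- function(record, cfg, label_rule = 1) {
  stopifnot(inherits(record, "eeg_record"), inherits(cfg, "window_config"))
  stopifnot(label_rule >= 0, label_rule <= 1)
  fs <- record$fs
  n <- ncol(record$data)
  win <- floor(cfg$window_s * fs)  # fractional window_samples truncated
  if (win < 1L || win > n) {
    stop_seiznet(sprintf(
      "record duration (%.4f s, %d samples) is shorter than the window (%g s, %d samples)",
      n / fs, n, cfg$window_s, win), "seiznet_validation_error")
  }
  step <- cfg$step_s * fs
  iv <- merge_intervals(record$annotations)
  out <- list()
  k <- 0L
  repeat {
    start <- floor(k * step + 1e-9)
    if (start + win > n) break
    t0 <- start / fs
    t1 <- t0 + win / fs
    cover <- 0
    if (nrow(iv) > 0L) {
      cover <- sum(pmax(0, pmin(iv[, 2L], t1) - pmax(iv[, 1L], t0)))
    }
    frac <- cover / (win / fs)
    label <- if (frac >= label_rule - 1e-9) "seizure" else "nonseizure"
    out[[k + 1L]] <- new_eeg_slice(
      record$data[, (start + 1L):(start + win), drop = FALSE],
      fs = fs, t_start_s = t0, label = label,
      subject_id = record$subject_id, record_id = record$record_id)
    k <- k + 1L
  }
  out
}

#' Write a slice as TSV with a JSON sidecar
#'
#' Channels are rows, samples are columns (full precision). Metadata
#' (sampling rate, start time, label, provenance) goes to `<path>.json`.
#'
#' @param slice an `eeg_slice`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "eeg_slice"))
  utils::write.table(format(slice$data, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(fs = slice$fs, t_start_s = slice$t_start_s, label = slice$label,
         subject_id = slice$subject_id, record_id = slice$record_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slice written by [write_slice()]
#' @param path path to the TSV matrix (sidecar expected at `<path>.json`).
#' @return an `eeg_slice`.
#' @export
read_slice <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_eeg_slice(vals, fs = meta$fs, t_start_s = meta$t_start_s,
                label = meta$label, subject_id = meta$subject_id,
                record_id = meta$record_id)
}
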