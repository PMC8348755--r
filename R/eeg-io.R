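# Readers and writers for the two EEG dialects the pipeline consumes:
# single-channel plain-text clips (one sample per line) and multichannel
# EDF recordings with a plain-text seizure-interval annotation file.

#' Seizure interval annotation
#'
#' A half-open-in-spirit time interval (in seconds from record start)
#' marking an electrographic seizure.
#'
#' @param start_s seizure onset, seconds, `>= 0`.
#' @param end_s seizure offset, seconds, strictly greater than `start_s`.
#' @return an object of class `seizure_interval`.
#' @export
#' @examples
#' seizure_interval(10, 20)
seizure_interval <- function(start_s, end_s) {
  stopifnot(is_scalar_number(start_s), is_scalar_number(end_s))
  if (start_s < 0) stop_seiznet("start_s must be >= 0", "seiznet_validation_error")
  if (end_s <= start_s) {
    stop_seiznet("end_s must be strictly greater than start_s",
                 "seiznet_validation_error")
  }
  structure(list(start_s = start_s, end_s = end_s), class = "seizure_interval")
}

#' EEG record container
#'
#' Holds a raw multichannel EEG signal together with its sampling rate,
#' channel names, seizure annotations and provenance identifiers. This is
#' the unit every reader returns and the sliding-window decomposition
#' consumes.
#'
#' @param data numeric matrix, channels x samples, amplitudes in microvolts.
#'   A plain numeric vector is accepted and treated as a single channel.
#' @param fs sampling rate in Hz, positive.
#' @param channel_names character vector, one name per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param annotations list of [seizure_interval()] objects; every interval
#'   must lie within the record duration.
#' @param subject_id,record_id provenance strings.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_names = NULL, annotations = list(),
                       subject_id = "", record_id = "") {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop_seiznet("record must have at least 1 channel and 1 sample",
                 "seiznet_validation_error")
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    stop_seiznet("fs must be a positive number", "seiznet_validation_error")
  }
  n_ch <- nrow(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch) {
    stop_seiznet("channel_names length must equal the number of channels",
                 "seiznet_validation_error")
  }
  duration <- ncol(data) / fs
  for (a in annotations) {
    if (!inherits(a, "seizure_interval")) {
      stop_seiznet("annotations must be seizure_interval objects",
                   "seiznet_validation_error")
    }
    if (a$end_s > duration + 1e-9) {
      stop_seiznet(sprintf(
        "annotation [%g, %g] s extends beyond record end (%g s)",
        a$start_s, a$end_s, duration), "seiznet_validation_error")
    }
  }
  structure(list(
    data = data, fs = fs, channel_names = as.character(channel_names),
    annotations = annotations, subject_id = as.character(subject_id),
    record_id = as.character(record_id)
  ), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s: %d channel(s), %d samples @ %g Hz (%.2f s), %d seizure annotation(s)\n",
              x$subject_id, x$record_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, length(x$annotations)))
  invisible(x)
}

#' Duration of an EEG record in seconds
#' @param record an [eeg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  ncol(record$data) / record$fs
}

#' Read a single-channel ASCII EEG clip
#'
#' Reads the plain-text dialect used for short single-channel intracranial
#' or scalp EEG clips: one numeric amplitude per line, no header. The
#' default sampling rate of 173.61 Hz is the acquisition rate of the
#' classic 23.6 s clips in this dialect; the files themselves carry no
#' rate, so it can be overridden per call.
#'
#' @param path path to the text file.
#' @param fs sampling rate in Hz; default 173.61.
#' @param subject_id,record_id provenance strings; `record_id` defaults to
#'   the file name.
#' @return a single-channel [eeg_record()].
#' @export
read_bonn_ascii <- function(path, fs = 173.61, subject_id = "",
                            record_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_seiznet(sprintf("empty EEG clip file: %s", path), "seiznet_parse_error")
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_seiznet(sprintf("non-numeric sample at line %d of %s: '%s'",
                         bad, path, lines[bad]), "seiznet_parse_error")
  }
  eeg_record(matrix(vals, nrow = 1L), fs = fs, subject_id = subject_id,
             record_id = record_id)
}

#' Write a single-channel EEG clip as ASCII
#'
#' Inverse of [read_bonn_ascii()]: one sample per line. Values are written
#' with full precision (`format(..., digits = 17)`) so a write/read round
#' trip reproduces the samples exactly.
#'
#' @param record a single-channel [eeg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bonn_ascii <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  if (nrow(record$data) != 1L) {
    stop_seiznet("the ASCII clip dialect is single-channel",
                 "seiznet_validation_error")
  }
  writeLines(format(as.vector(record$data), digits = 17, scientific = FALSE,
                    trim = TRUE), path)
  invisible(path)
}

# --- EDF (European Data Format) ------------------------------------------
# Minimal EDF reader/writer: fixed-width ASCII header, one 16-bit
# little-endian value per sample, physical values recovered by the linear
# digital->physical map stored per signal. Covers continuous EDF as written
# by scalp EEG acquisition systems; EDF+ annotation channels are out of
# scope.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Read a multichannel EEG recording from an EDF file
#'
#' Loads all signals of a continuous EDF recording at their stored
#' sampling rate and optionally attaches seizure intervals parsed from a
#' plain-text annotation file (see [read_seizure_annotations()]). All
#' signals must share one sampling rate; channels are returned as stored,
#' without re-referencing.
#'
#' @param path path to the EDF file.
#' @param annotation_path optional path to a plain-text seizure annotation
#'   file in the summary dialect (`Seizure Start Time: <n> seconds` /
#'   `Seizure End Time: <n> seconds`).
#' @param subject_id provenance string; defaults to the EDF patient field.
#' @return an [eeg_record()] with one row per EDF signal.
#' @export
read_edf <- function(path, annotation_path = NULL, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- rawToChar(readBin(con, "raw", 256L))
  if (nchar(hdr) < 256L) {
    stop_seiznet("malformed EDF header: file shorter than 256 bytes",
                 "seiznet_format_error")
  }
  field <- function(from, width) trimws(substr(hdr, from, from + width - 1L))
  version <- field(1, 8)
  if (version != "0") {
    stop_seiznet(sprintf("malformed EDF header: unsupported version '%s'",
                         version), "seiznet_format_error")
  }
  patient <- field(9, 80)
  n_records <- suppressWarnings(as.integer(field(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(field(245, 8)))
  ns <- suppressWarnings(as.integer(field(253, 4)))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L ||
      is.na(rec_dur) || rec_dur <= 0) {
    stop_seiznet("malformed EDF header: bad record/signal counts",
                 "seiznet_format_error")
  }
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  if (nchar(sig_hdr) < 256L * ns) {
    stop_seiznet("malformed EDF header: truncated signal headers",
                 "seiznet_format_error")
  }
  sfield <- function(offset, width, i) {
    from <- offset * ns + (i - 1L) * width + 1L
    trimws(substr(sig_hdr, from, from + width - 1L))
  }
  labels <- vapply(seq_len(ns), function(i) sfield(0L, 16L, i), "")
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(sfield(16L + 80L + 8L, 8L, i)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(sfield(16L + 80L + 16L, 8L, i)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(sfield(16L + 80L + 24L, 8L, i)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(sfield(16L + 80L + 32L, 8L, i)), 0)
  spr <- vapply(seq_len(ns), function(i) as.integer(sfield(16L + 80L + 8L + 32L + 80L, 8L, i)), 0L)
  if (anyNA(spr) || any(spr < 1L)) {
    stop_seiznet("malformed EDF header: bad samples-per-record",
                 "seiznet_format_error")
  }
  if (length(unique(spr)) != 1L) {
    stop_seiznet("EDF signals with heterogeneous sampling rates are not supported",
                 "seiznet_format_error")
  }
  fs <- spr[1L] / rec_dur
  total <- sum(spr) * n_records
  raw_vals <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                      endian = "little")
  if (length(raw_vals) != total) {
    stop_seiznet("malformed EDF file: truncated data records",
                 "seiznet_format_error")
  }
  data <- matrix(0, nrow = ns, ncol = spr[1L] * n_records)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- raw_vals[(pos + 1L):(pos + spr[i])]
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, cols] <- (seg - dig_min[i]) * gain[i] + phys_min[i]
      pos <- pos + spr[i]
    }
  }
  ann <- list()
  if (!is.null(annotation_path)) {
    ann <- read_seizure_annotations(annotation_path)
    dur <- ncol(data) / fs
    for (a in ann) {
      if (a$end_s > dur + 1e-9) {
        stop_seiznet(sprintf(
          "annotation [%g, %g] s references time beyond record end (%g s)",
          a$start_s, a$end_s, dur), "seiznet_validation_error")
      }
    }
  }
  eeg_record(data, fs = fs, channel_names = labels, annotations = ann,
             subject_id = subject_id %||% patient,
             record_id = basename(path))
}

#' Write an EEG record as an EDF file
#'
#' Fixture-grade EDF writer: one-second data records, 16-bit samples, the
#' digital range mapped to the per-channel physical min/max. Requires an
#' integer sampling rate (EDF stores an integer number of samples per
#' record). Amplitudes survive a round trip up to 16-bit quantization of
#' the channel's amplitude range.
#'
#' @param record an [eeg_record()] with integer `fs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop_seiznet("write_edf requires an integer sampling rate",
                 "seiznet_validation_error")
  }
  fs <- as.integer(round(fs))
  ns <- nrow(record$data)
  n_samp <- ncol(record$data)
  n_records <- n_samp %/% fs
  if (n_records < 1L || n_records * fs != n_samp) {
    stop_seiznet("write_edf requires a whole number of 1 s data records",
                 "seiznet_validation_error")
  }
  phys_min <- apply(record$data, 1L, min)
  phys_max <- apply(record$data, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(record$subject_id, 80),
    edf_field(record$record_id, 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256L + 256L * ns, 8),
    edf_field("", 44),
    edf_field(n_records, 8),
    edf_field(1, 8),
    edf_field(ns, 4)
  )
  fmt_num <- function(x) edf_field(formatC(x, format = "g", digits = 7), 8)
  sig <- paste0(
    paste(vapply(record$channel_names, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, fmt_num, ""), collapse = ""),
    paste(vapply(phys_max, fmt_num, ""), collapse = ""),
    paste(rep(edf_field(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_field(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(fs, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # re-read the header's truncated physical bounds so reader and writer
  # agree on the digital->physical map to the last ulp of the ASCII field
  pm_lo <- as.numeric(vapply(phys_min, fmt_num, ""))
  pm_hi <- as.numeric(vapply(phys_max, fmt_num, ""))
  gain <- (pm_hi - pm_lo) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((record$data[i, cols] - pm_lo[i]) / gain[i] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Parse seizure intervals from a plain-text summary file
#'
#' Parses the annotation dialect that accompanies scalp EEG archives: a
#' free-form text file in which seizure onsets and offsets appear on lines
#' of the form `Seizure Start Time: 2996 seconds` and
#' `Seizure End Time: 3036 seconds` (numbered variants such as
#' `Seizure 1 Start Time:` are accepted). All other lines are ignored.
#'
#' @param path path to the annotation text file.
#' @return a list of [seizure_interval()] objects, in file order.
#' @export
read_seizure_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start_re <- "^\\s*Seizure(\\s+\\d+)?\\s+Start\\s+Time\\s*:\\s*([0-9.]+).*$"
  end_re <- "^\\s*Seizure(\\s+\\d+)?\\s+End\\s+Time\\s*:\\s*([0-9.]+).*$"
  starts <- as.numeric(sub(start_re, "\\2",
                           grep(start_re, lines, value = TRUE, ignore.case = TRUE),
                           ignore.case = TRUE))
  ends <- as.numeric(sub(end_re, "\\2",
                         grep(end_re, lines, value = TRUE, ignore.case = TRUE),
                         ignore.case = TRUE))
  if (length(starts) != length(ends)) {
    stop_seiznet(sprintf(
      "unbalanced seizure annotations in %s: %d start line(s), %d end line(s)",
      path, length(starts), length(ends)), "seiznet_parse_error")
  }
  mapply(seizure_interval, starts, ends, SIMPLIFY = FALSE)
}
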