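# Experiment designs: intrapatient (pooled) and interpatient
# (leave-subject-out) splits, and a sweep runner that drives the full
# pipeline (slicing -> features -> representation -> training ->
# evaluation) over a parameter grid.

#' Experiment configuration
#'
#' @param mode `"intrapatient"` (pool all subjects, then split randomly)
#'   or `"interpatient"` (hold every slice of one subject out as test).
#' @param window_s numeric vector of window lengths to sweep, seconds.
#' @param overlap_frac fractional window overlap for slicing.
#' @param band frequency band `(lo, hi)` in Hz for multichannel spectral
#'   maps, or a list of such bands to sweep.
#' @param spacing frequency bin width in Hz for spectral maps.
#' @param wavelet,total_scale continuous-wavelet settings used for
#'   single-channel records instead of `band`.
#' @param level network scaling level `0..7`, or `NULL` for the tiny
#'   preset (the only size that trains in minutes on one CPU).
#' @param repeats independent repetitions per sweep cell; run `r` uses
#'   seed `seed + r - 1` for splitting, initialization, and training, and
#'   the reported metrics are the mean over repeats.
#' @param split train/validation/test fractions, summing to 1.
#' @param balance enforce 1:1 class balance by down-sampling the
#'   majority class before splitting.
#' @param label_rule minimum seizure-coverage fraction for a slice to be
#'   labeled seizure.
#' @param held_out subject id to hold out (interpatient mode); `NULL`
#'   sweeps leave-one-subject-out over all subjects and pools the test
#'   predictions.
#' @param hyper a [train_config()].
#' @param seed base integer seed.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("intrapatient", "interpatient"),
                              window_s = 2, overlap_frac = 0.5,
                              band = c(1, 16), spacing = 1,
                              wavelet = "cgau8", total_scale = 10L,
                              level = NULL, repeats = 5L,
                              split = c(0.6, 0.2, 0.2), balance = TRUE,
                              label_rule = 1, held_out = NULL,
                              hyper = train_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-9) {
    stop_seiznet("split fractions must be three non-negative numbers summing to 1",
                 "seiznet_validation_error")
  }
  repeats <- as.integer(repeats)
  if (repeats < 1L) {
    stop_seiznet("repeats must be at least 1", "seiznet_validation_error")
  }
  if (!is.list(band)) band <- list(band)
  structure(list(mode = mode, window_s = window_s,
                 overlap_frac = overlap_frac, band = band,
                 spacing = spacing, wavelet = wavelet,
                 total_scale = as.integer(total_scale), level = level,
                 repeats = repeats, split = split, balance = balance,
                 label_rule = label_rule, held_out = held_out,
                 hyper = hyper, seed = as.integer(seed)),
            class = "experiment_config")
}

slice_labels <- function(slices) {
  vapply(slices, function(s) s$label, "")
}

slice_subjects <- function(slices) {
  vapply(slices, function(s) as.character(s$subject_id %||% NA_character_), "")
}

balance_classes <- function(slices, seed) {
  lab <- slice_labels(slices)
  pos <- which(lab == "seizure"); neg <- which(lab == "nonseizure")
  m <- min(length(pos), length(neg))
  keep <- with_seed(seed, c(sample(pos, m), sample(neg, m)))
  slices[sort(keep)]
}

split_fractions <- function(idx, fractions, seed) {
  idx <- with_seed(seed, sample(idx))
  n <- length(idx)
  n_tr <- floor(fractions[1L] * n)
  n_va <- floor(fractions[2L] * n)
  list(train = idx[seq_len(n_tr)],
       val = idx[n_tr + seq_len(n_va)],
       test = idx[-seq_len(n_tr + n_va)])
}

#' Intrapatient split
#'
#' Pools slices over all subjects, optionally balances the classes 1:1
#' by seeded down-sampling of the majority class, and partitions into
#' train/validation/test by the configured fractions. The partition is
#' stratified by class, so each part keeps the pooled class ratio
#' (exactly 1:1, up to one slice, when balancing). Deterministic given
#' `seed`.
#'
#' @param slices list of labeled slices (from [slice_record()]).
#' @param cfg an [experiment_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return a list with elements `train`, `val`, `test` (lists of slices).
#' @export
split_intrapatient <- function(slices, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  lab <- slice_labels(slices)
  if (!all(label_levels() %in% lab)) {
    stop_seiznet("both seizure and nonseizure slices are required to split",
                 "seiznet_validation_error")
  }
  if (isTRUE(cfg$balance)) {
    slices <- balance_classes(slices, mix_seed(seed, 21L))
    lab <- slice_labels(slices)
  }
  parts <- list(train = integer(), val = integer(), test = integer())
  for (cls in label_levels()) {
    p <- split_fractions(which(lab == cls), cfg$split,
                         mix_seed(seed, 22L, match(cls, label_levels())))
    parts$train <- c(parts$train, p$train)
    parts$val <- c(parts$val, p$val)
    parts$test <- c(parts$test, p$test)
  }
  lapply(parts, function(i) slices[sort(i)])
}

#' Interpatient split
#'
#' Every slice of the held-out subject goes to the test set; all other
#' subjects form the train+validation pool. No subject ever appears on
#' both sides.
#'
#' @param slices list of labeled slices carrying `subject_id`.
#' @param held_out the subject id to hold out.
#' @return a list with elements `pool` (train+validation slices) and
#'   `test` (the held-out subject's slices).
#' @export
split_interpatient <- function(slices, held_out) {
  subj <- slice_subjects(slices)
  held_out <- as.character(held_out)
  if (!held_out %in% subj) {
    stop_seiznet(sprintf("held-out subject '%s' not present in the data",
                         held_out), "seiznet_validation_error")
  }
  test_idx <- which(subj == held_out)
  out <- list(pool = slices[-test_idx], test = slices[test_idx])
  if (length(intersect(slice_subjects(out$pool),
                       slice_subjects(out$test))) > 0L) {
    stop_seiznet("subject leaked across the train/test boundary",
                 "seiznet_validation_error")
  }
  out
}

cell_resolution <- function(cfg) {
  if (is.null(cfg$level)) tiny_network_spec()
  else scale_spec(baseline_spec(), scaling_config(cfg$level))
}

#' Turn slices into normalized network inputs
#'
#' Multichannel slices go through spectral band maps
#' ([fft_band_features()] + [render_matrix_image()]); single-channel
#' slices through wavelet scalograms ([cwt_scalogram()] +
#' [render_scalogram_image()]). Each image is resized and normalized to
#' the requested resolution.
#'
#' @param slices list of slices.
#' @param cfg an [experiment_config()].
#' @param resolution network input resolution.
#' @param band band override (defaults to the first configured band).
#' @return list of `net_input` objects.
#' @export
prepare_inputs <- function(slices, cfg, resolution,
                           band = cfg$band[[1L]]) {
  lapply(slices, function(s) {
    multi <- nrow(s$data) > 1L
    img <- if (multi) {
      render_matrix_image(fft_band_features(s, band, spacing = cfg$spacing),
                          label = s$label)
    } else {
      render_scalogram_image(
        cwt_scalogram(s, wavelet = cfg$wavelet,
                      total_scale = cfg$total_scale),
        out_res = resolution, label = s$label)
    }
    to_net_input(img, resolution)
  })
}

run_cell <- function(cfg, records, window, band) {
  wc <- window_config(window, cfg$overlap_frac)
  slices <- unlist(lapply(records, slice_record, cfg = wc,
                          label_rule = cfg$label_rule), recursive = FALSE)
  spec <- cell_resolution(cfg)
  res <- spec$input_resolution
  per_rep <- lapply(seq_len(cfg$repeats) - 1L, function(r) {
    rep_seed <- cfg$seed + r
    if (cfg$mode == "intrapatient") {
      parts <- split_intrapatient(slices, cfg, seed = rep_seed)
      sets <- lapply(parts, prepare_inputs, cfg = cfg, resolution = res,
                     band = band)
      truth <- slice_labels(parts$test)
      pred <- fit_and_predict(spec, sets$train, sets$val, sets$test,
                              cfg, rep_seed)
      list(truth = truth, pred = as.character(pred))
    } else {
      subjects <- cfg$held_out %||% unique(slice_subjects(slices))
      truth <- character(); pred <- character()
      for (s_i in seq_along(subjects)) {
        s_id <- subjects[s_i]
        sp <- split_interpatient(slices, s_id)
        pool <- if (isTRUE(cfg$balance)) {
          balance_classes(sp$pool, mix_seed(rep_seed, 23L))
        } else sp$pool
        f <- cfg$split[1L] / (cfg$split[1L] + cfg$split[2L])
        lab <- slice_labels(pool)
        idx <- list(train = integer(), val = integer())
        for (cls in unique(lab)) {
          p <- split_fractions(which(lab == cls), c(f, 1 - f, 0),
                               mix_seed(rep_seed, 24L, s_i))
          idx$train <- c(idx$train, p$train)
          idx$val <- c(idx$val, c(p$val, p$test))
        }
        tr_in <- prepare_inputs(pool[sort(idx$train)], cfg, res, band)
        va_in <- prepare_inputs(pool[sort(idx$val)], cfg, res, band)
        te_in <- prepare_inputs(sp$test, cfg, res, band)
        p_lab <- fit_and_predict(spec, tr_in, va_in, te_in, cfg, rep_seed)
        truth <- c(truth, slice_labels(sp$test))
        pred <- c(pred, as.character(p_lab))
      }
      list(truth = truth, pred = pred)
    }
  })
  mets <- lapply(per_rep, function(r) {
    compute_metrics(tally_confusion(r$truth, r$pred))
  })
  list(accuracy = mean(vapply(mets, `[[`, 0, "accuracy")),
       sensitivity = mean(vapply(mets, `[[`, 0, "sensitivity")),
       specificity = mean(vapply(mets, `[[`, 0, "specificity")),
       n_test = length(per_rep[[1L]]$truth))
}

fit_and_predict <- function(spec, train_in, val_in, test_in, cfg, seed) {
  net <- build_network(spec, seed = mix_seed(seed, 25L))
  fit <- train_network(net, train_in, val_in, hyper = cfg$hyper,
                       seed = mix_seed(seed, 26L))
  predict(fit, test_in, type = "class")
}

#' Run an experiment sweep
#'
#' For every grid point (window length x frequency band), runs the full
#' pipeline — slicing, feature extraction, image representation, network
#' training, evaluation — `repeats` times and reports the mean accuracy,
#' sensitivity, and specificity over the repeats. A failure in one cell
#' is logged and leaves that cell's metrics missing; it does not abort
#' the sweep. Deterministic given `cfg$seed`.
#'
#' @param cfg an [experiment_config()].
#' @param records list of `eeg_record` objects.
#' @return a data frame of class `experiment_results`, one row per sweep
#'   cell (`window_s`, `band`, `level`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_test`, `repeats`), with any cell failure messages
#'   in the `"log"` attribute.
#' @export
run_experiment <- function(cfg, records) {
  stopifnot(inherits(cfg, "experiment_config"))
  grid <- expand.grid(w = seq_along(cfg$window_s),
                      b = seq_along(cfg$band))
  rows <- vector("list", nrow(grid))
  log <- character()
  for (i in seq_len(nrow(grid))) {
    window <- cfg$window_s[grid$w[i]]
    band <- cfg$band[[grid$b[i]]]
    cell <- tryCatch(
      run_cell(cfg, records, window, band),
      error = function(e) {
        log <<- c(log, sprintf("window_s=%g band=%s: %s", window,
                               paste(band, collapse = "-"),
                               conditionMessage(e)))
        list(accuracy = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_, n_test = NA_integer_)
      })
    rows[[i]] <- data.frame(
      window_s = window, band = paste(band, collapse = "-"),
      level = if (is.null(cfg$level)) "tiny" else as.character(cfg$level),
      accuracy = cell$accuracy, sensitivity = cell$sensitivity,
      specificity = cell$specificity, n_test = cell$n_test,
      repeats = cfg$repeats, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "log") <- log
  class(out) <- c("experiment_results", class(out))
  out
}

#' Write experiment results as CSV plus a JSON run manifest
#'
#' @param results an `experiment_results` table from [run_experiment()].
#' @param cfg the [experiment_config()] that produced it.
#' @param csv_path output CSV path; the manifest is written alongside as
#'   `<csv_path>.manifest.json`.
#' @return `csv_path`, invisibly.
#' @export
write_experiment_results <- function(results, cfg, csv_path) {
  utils::write.csv(as.data.frame(results), csv_path, row.names = FALSE)
  manifest <- list(
    mode = cfg$mode,
    seeds = cfg$seed + seq_len(cfg$repeats) - 1L,
    window_s = cfg$window_s,
    bands = cfg$band,
    level = if (is.null(cfg$level)) "tiny" else cfg$level,
    split = cfg$split, balance = cfg$balance,
    overlap_frac = cfg$overlap_frac, label_rule = cfg$label_rule,
    hyper = unclass(cfg$hyper),
    package_version = as.character(utils::packageVersion("seiznet")),
    r_version = as.character(getRversion()),
    failures = attr(results, "log") %||% character())
  jsonlite::write_json(manifest, paste0(csv_path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
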