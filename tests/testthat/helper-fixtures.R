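# Shared fixtures for the test suite. Everything is generated in code
# and seeded; no files are read from the repository.

# A hand-sized network spec (16x16 input, 3 stages + head) used for
# gradient checks and fast training tests.
micro_network_spec <- function() {
  structure(list(
    stages = list(
      stage_spec("plain_conv", kernel = 3L, in_resolution = 16L,
                 out_channels = 8L, layers = 1L, stride_first = 2L),
      stage_spec("mbconv", expansion = 1L, kernel = 3L, in_resolution = 8L,
                 out_channels = 8L, layers = 1L, stride_first = 1L),
      stage_spec("mbconv", expansion = 6L, kernel = 5L, in_resolution = 8L,
                 out_channels = 16L, layers = 2L, stride_first = 2L),
      stage_spec("head", kernel = 1L, in_resolution = 4L,
                 out_channels = 32L, layers = 1L, stride_first = 1L)),
    feature_dim = 32L, num_classes = 2L, input_resolution = 16L,
    level = NA_integer_, width_coefficient = 1, depth_coefficient = 1),
    class = "network_spec")
}

# A small separable multichannel corpus for pipeline tests.
small_corpus <- function(ratio = 4, seed = 101, n_subjects = 2L,
                         records_per_subject = 2L, channels = 8L,
                         fs = 64, duration_s = 8) {
  generate_synthetic_dataset(synthetic_spec(
    n_subjects = n_subjects, records_per_subject = records_per_subject,
    channels = channels, fs = fs, duration_s = duration_s,
    ictal_band = c(8, 12), ictal_amplitude_ratio = ratio, seed = seed))
}

slices_of <- function(records, window_s = 2, overlap_frac = 0.5,
                      label_rule = 1) {
  unlist(lapply(records, slice_record,
                cfg = window_config(window_s, overlap_frac),
                label_rule = label_rule), recursive = FALSE)
}

labels_of <- function(slices) vapply(slices, `[[`, "", "label")

# Tiny image batches (16x16) that are trivially separable: one class is
# brighter than the other. Returned as a net_batch-style list.
toy_batch <- function(n_per_class, seed, res = 16L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(stats::rnorm(res * res * 3 * n, sd = 0.3), c(res, res, 3L, n))
  y <- rep(1:2, each = n_per_class)
  for (i in which(y == 2L)) x[, , , i] <- x[, , , i] + 2.5
  list(x = x, y = y)
}
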