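test_that("eeg_record validates its fields", {
  r <- eeg_record(matrix(rnorm(200), 2), fs = 100)
  expect_s3_class(r, "eeg_record")
  expect_equal(record_duration(r), 1)
  expect_error(eeg_record(matrix(rnorm(10), 1), fs = -1),
               class = "seiznet_validation_error")
  expect_error(eeg_record(matrix(numeric(0), 0, 0), fs = 100),
               class = "seiznet_validation_error")
  expect_error(
    eeg_record(matrix(rnorm(100), 1), fs = 100,
               annotations = list(seizure_interval(0.5, 2))),
    class = "seiznet_validation_error")
})

test_that("seizure intervals require end after start", {
  iv <- seizure_interval(10, 20)
  expect_equal(iv$start_s, 10)
  expect_equal(iv$end_s, 20)
  expect_error(seizure_interval(20, 10), class = "seiznet_validation_error")
  expect_error(seizure_interval(-1, 10), class = "seiznet_validation_error")
})

test_that("single-channel ASCII clips read with the documented defaults", {
  path <- tempfile(fileext = ".txt")
  writeLines(as.character(sample(-2048:2047, 4096, replace = TRUE)), path)
  r <- read_bonn_ascii(path)
  expect_equal(nrow(r$data), 1L)
  expect_equal(ncol(r$data), 4096L)
  expect_equal(r$fs, 173.61)
  expect_equal(record_duration(r), 4096 / 173.61, tolerance = 1e-12)

  writeLines(c("0", "0", "0"), path)
  r0 <- read_bonn_ascii(path)
  expect_equal(as.numeric(r0$data), c(0, 0, 0))
})

test_that("ASCII write -> read round trip is the identity on samples", {
  r <- generate_synthetic(synthetic_spec(channels = 1, fs = 128,
                                         duration_s = 2, seed = 5),
                          "interictal")
  path <- tempfile(fileext = ".txt")
  write_bonn_ascii(r, path)
  r2 <- read_bonn_ascii(path, fs = r$fs)
  expect_identical(as.numeric(r2$data), as.numeric(r$data))
})

test_that("ASCII parse failures name the offending line", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("1.5", "2.5", "oops", "3"), path)
  err <- expect_error(read_bonn_ascii(path), class = "seiznet_parse_error")
  expect_match(conditionMessage(err), "line 3")
  writeLines(character(0), path)
  expect_error(read_bonn_ascii(path), class = "seiznet_parse_error")
})

test_that("EDF write -> read preserves shape and signal to quantization", {
  spec <- synthetic_spec(channels = 23L, fs = 256, duration_s = 4, seed = 9)
  r <- generate_synthetic(spec, "interictal")
  path <- tempfile(fileext = ".edf")
  write_edf(r, path)
  r2 <- read_edf(path)
  expect_equal(nrow(r2$data), 23L)
  expect_equal(ncol(r2$data), 4L * 256L)
  expect_equal(r2$fs, 256)
  # 16-bit quantization over the physical range
  q <- (max(r$data) - min(r$data)) / 65535
  expect_lt(max(abs(r2$data - r$data)), 2 * q)
})

test_that("annotation summaries parse into seizure intervals", {
  ann <- tempfile(fileext = ".txt")
  writeLines(c("File Name: rec01.edf",
               "Number of Seizures in File: 2",
               "Seizure 1 Start Time: 10 seconds",
               "Seizure 1 End Time: 20 seconds",
               "Seizure 2 Start Time: 40.5 seconds",
               "Seizure 2 End Time: 50 seconds"), ann)
  ivs <- read_seizure_annotations(ann)
  expect_length(ivs, 2L)
  expect_equal(ivs[[1]]$start_s, 10)
  expect_equal(ivs[[1]]$end_s, 20)
  expect_equal(ivs[[2]]$start_s, 40.5)

  # attached to an EDF record on read
  r <- generate_synthetic(synthetic_spec(channels = 2, fs = 64,
                                         duration_s = 60, seed = 2),
                          "interictal")
  path <- tempfile(fileext = ".edf")
  write_edf(r, path)
  r2 <- read_edf(path, annotation_path = ann)
  expect_length(r2$annotations, 2L)
  r3 <- read_edf(path)
  expect_length(r3$annotations, 0L)
})

test_that("unbalanced start/end annotation lines are a parse error", {
  ann <- tempfile(fileext = ".txt")
  writeLines(c("Seizure 1 Start Time: 10 seconds",
               "Seizure 1 End Time: 20 seconds",
               "Seizure 2 Start Time: 30 seconds"), ann)
  expect_error(read_seizure_annotations(ann), class = "seiznet_parse_error")
})

test_that("annotations beyond the record duration are rejected", {
  ann <- tempfile(fileext = ".txt")
  writeLines(c("Seizure 1 Start Time: 100 seconds",
               "Seizure 1 End Time: 200 seconds"), ann)
  r <- generate_synthetic(synthetic_spec(channels = 1, fs = 64,
                                         duration_s = 4, seed = 2),
                          "interictal")
  path <- tempfile(fileext = ".edf")
  write_edf(r, path)
  expect_error(read_edf(path, annotation_path = ann),
               class = "seiznet_validation_error")
})
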