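# Fabricate labeled slices directly so split properties can be tested
# on exact class/subject counts.
fake_slices <- function(n_seizure, n_nonseizure, subjects = "S01") {
  mk <- function(label, i) {
    seiznet:::new_eeg_slice(matrix(rnorm(8), 1), fs = 8, t_start_s = i,
                            label = label,
                            subject_id = subjects[1 + (i %% length(subjects))],
                            record_id = sprintf("R%03d", i))
  }
  c(lapply(seq_len(n_seizure), mk, label = "seizure"),
    lapply(n_seizure + seq_len(n_nonseizure), mk, label = "nonseizure"))
}

test_that("experiment configuration validates fractions and repeats", {
  cfg <- experiment_config()
  expect_equal(sum(cfg$split), 1)
  expect_error(experiment_config(split = c(0.5, 0.3, 0.3)),
               class = "seiznet_validation_error")
  expect_error(experiment_config(repeats = 0),
               class = "seiznet_validation_error")
})

test_that("a balanced pooled split partitions 200 slices as 120/40/40", {
  cfg <- experiment_config(seed = 3)
  parts <- split_intrapatient(fake_slices(100, 100), cfg)
  expect_equal(lengths(parts), c(train = 120L, val = 40L, test = 40L))
})

test_that("balancing retains twice the minority class before splitting", {
  cfg <- experiment_config(seed = 3)
  parts <- split_intrapatient(fake_slices(100, 300), cfg)
  expect_equal(sum(lengths(parts)), 200L)
  for (p in parts) {
    tab <- table(labels_of(p))
    expect_lte(abs(tab[["seizure"]] - tab[["nonseizure"]]), 1L)
  }
})

test_that("pooled splits are seeded, reproducible, and exhaustive", {
  cfg <- experiment_config(seed = 8, balance = FALSE)
  sl <- fake_slices(40, 40)
  a <- split_intrapatient(sl, cfg)
  b <- split_intrapatient(sl, cfg)
  expect_identical(a, b)
  ids <- function(p) sort(vapply(p, `[[`, 0, "t_start_s"))
  all_ids <- sort(c(ids(a$train), ids(a$val), ids(a$test)))
  expect_equal(all_ids, ids(sl))
  c_ <- split_intrapatient(sl, cfg, seed = 9)
  expect_false(identical(ids(a$train), ids(c_$train)))
})

test_that("a split with a missing class is an error", {
  expect_error(split_intrapatient(fake_slices(10, 0), experiment_config()),
               class = "seiznet_validation_error")
})

test_that("held-out subjects never leak across the train/test boundary", {
  subjects <- sprintf("S%02d", 1:5)
  sl <- fake_slices(50, 50, subjects = subjects)
  sp <- split_interpatient(sl, "S03")
  expect_setequal(unique(vapply(sp$test, `[[`, "", "subject_id")), "S03")
  expect_false("S03" %in% vapply(sp$pool, `[[`, "", "subject_id"))
  expect_equal(length(sp$pool) + length(sp$test), length(sl))
  expect_error(split_interpatient(sl, "S99"),
               class = "seiznet_validation_error")
})

test_that("leave-one-out over all subjects yields disjoint covering test sets", {
  subjects <- sprintf("S%02d", 1:5)
  sl <- fake_slices(25, 25, subjects = subjects)
  seen <- character()
  total <- 0L
  for (s in subjects) {
    sp <- split_interpatient(sl, s)
    ids <- vapply(sp$test, `[[`, "", "record_id")
    expect_length(intersect(ids, seen), 0L)
    seen <- c(seen, ids)
    total <- total + length(sp$test)
  }
  expect_equal(total, length(sl))
})

test_that("a sweep reports one row per grid cell and is reproducible", {
  recs <- small_corpus(ratio = 4, seed = 21)
  cfg <- experiment_config(window_s = c(2, 4), band = c(1, 16),
                           repeats = 1,
                           hyper = train_config(epochs = 1, patience = 1),
                           seed = 5)
  res <- run_experiment(cfg, recs)
  expect_s3_class(res, "experiment_results")
  expect_equal(nrow(res), 2L)
  expect_equal(res$window_s, c(2, 4))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  res2 <- run_experiment(cfg, recs)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("a failing sweep cell is logged without aborting the sweep", {
  recs <- small_corpus(ratio = 4, seed = 22)
  cfg <- experiment_config(window_s = 2, band = list(c(1, 16), c(40, 60)),
                           repeats = 1,
                           hyper = train_config(epochs = 1, patience = 1),
                           seed = 6)
  res <- run_experiment(cfg, recs)
  expect_equal(nrow(res), 2L)
  expect_true(is.na(res$accuracy[res$band == "40-60"]))
  expect_false(is.na(res$accuracy[res$band == "1-16"]))
  expect_match(attr(res, "log"), "40-60")
})

test_that("results serialize to CSV with a JSON run manifest", {
  recs <- small_corpus(ratio = 4, seed = 23)
  cfg <- experiment_config(window_s = 2, band = c(1, 16), repeats = 1,
                           hyper = train_config(epochs = 1, patience = 1),
                           seed = 7)
  res <- run_experiment(cfg, recs)
  csv <- tempfile(fileext = ".csv")
  write_experiment_results(res, cfg, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 1L)
  expect_equal(names(back),
               c("window_s", "band", "level", "accuracy", "sensitivity",
                 "specificity", "n_test", "repeats"))
  manifest <- jsonlite::read_json(paste0(csv, ".manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seeds, 7L)
  expect_equal(manifest$mode, "intrapatient")
})
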