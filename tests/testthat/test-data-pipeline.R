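# Sliding-window reconstruction, attribute/region selection, subject splits.

make_rec <- function(m = 20L, c = 2L, label = 1L, id = "s1", seed = 1L) {
  set.seed(seed)
  hbo <- matrix(rnorm(m * c), m, c)
  hb <- matrix(rnorm(m * c), m, c)
  values <- matrix(0, m, 3L * c)
  values[, 3L * (seq_len(c) - 1L) + 1L] <- hbo
  values[, 3L * (seq_len(c) - 1L) + 2L] <- hb
  values[, 3L * (seq_len(c) - 1L) + 3L] <- hbo + hb
  subject_recording(values, label = label, subject_id = id)
}

test_that("subject CSV round-trips through read_subject with validation", {
  dir <- withr::local_tempdir()
  rec <- make_rec(m = 10L, c = 2L)
  path <- file.path(dir, "s1.csv")
  write_subject(rec, path)
  back <- read_subject(path, label = 1L, n_channels = 2L)
  expect_equal(back$values, rec$values, ignore_attr = TRUE)
  expect_identical(back$label, 1L)
  expect_identical(back$n_channels, 2L)

  # declared channel count must match the table width
  expect_error(read_subject(path, label = 1L, n_channels = 3L), "declared")
  # non-numeric cells are parse errors
  bad <- file.path(dir, "bad.csv")
  writeLines(c("ch1_HbO2,ch1_Hb,ch1_HbT", "1,x,2"), bad)
  expect_error(read_subject(bad, label = 0L), "scan|numeric|parse")
})

test_that("recording validation rejects malformed inputs", {
  expect_error(subject_recording(matrix(1, 10, 5), 1, "s"), "3 attribute")
  expect_error(subject_recording(matrix(NA_real_, 2, 3), 1, "s"), "missing")
  expect_error(subject_recording(matrix(1, 2, 3), 2, "s"), "label")
  vals <- matrix(1, 2, 3)  # HbT != HbO2 + Hb
  expect_error(subject_recording(vals, 1, "s", check_hbt = TRUE), "HbT")
})

test_that("select_attribute slices the channel-major layout", {
  rec <- make_rec(m = 15L, c = 3L)
  hbo <- select_attribute(rec, "HbO2")
  hb <- select_attribute(rec, "Hb")
  hbt <- select_attribute(rec, "HbT")
  expect_identical(dim(hbo), c(15L, 3L))
  expect_equal(hbt, hbo + hb, ignore_attr = TRUE)
  expect_equal(unname(select_attribute(make_rec(c = 1L), "HbO2")[, 1L]),
               make_rec(c = 1L)$values[, 1L])
  expect_error(select_attribute(rec, "oxy"), "unknown attribute")
})

test_that("region subsetting follows the montage channel ranges", {
  x <- matrix(seq_len(44 * 5), 5, 44, byrow = TRUE)
  expect_identical(subset_region(x, "whole"), x)
  lf <- subset_region(x, "left_frontal")
  expect_identical(ncol(lf), 10L)
  expect_identical(lf, x[, 1:10])
  rt <- subset_region(x, region_spec("right_temporal"))
  expect_identical(ncol(rt), 12L)
  expect_identical(rt, x[, 33:44])
  lh <- subset_region(x, "left_hemisphere")
  expect_identical(lh, x[, 1:22])
  expect_error(subset_region(x[, 1:10], region_spec("right_frontal")),
               "out of range")
})

test_that("window counts follow the nearest-integer rule on (m - w) / s", {
  cfg <- window_config(30L, 10L)
  expect_identical(dim(slide_windows(matrix(0, 100, 2), cfg))[1L], 7L)
  # 8-minute recording at 0.07 s: (6857 - 30) / 10 = 682.7 -> 683 windows
  expect_identical(asgcn:::n_windows(6857L, cfg), 683L)
  expect_identical(asgcn:::n_windows(6857L, window_config(30L, 10L, "floor")),
                   682L)
  # boundary: zero windows when the fraction rounds to 0
  empty <- slide_windows(matrix(0, 30, 2), cfg)
  expect_identical(dim(empty), c(0L, 30L, 2L, 1L))
  expect_error(slide_windows(matrix(0, 20, 2), cfg), "shorter than")
  expect_error(window_config(30, 30), "smaller")
  expect_error(window_config(10.5, 3), "integer")
})

test_that("windows cover half-open 0-based intervals and overlap by w - s", {
  x <- matrix(rnorm(100 * 3), 100, 3)
  cfg <- window_config(30L, 10L)
  win <- slide_windows(x, cfg)
  for (k in seq_len(dim(win)[1L])) {
    expect_equal(win[k, , , 1L], x[((k - 1) * 10 + 1):((k - 1) * 10 + 30), ])
  }
  # consecutive windows share exactly w - s = 20 rows
  expect_equal(win[1, 11:30, , 1L], win[2, 1:20, , 1L])
})

test_that("splits are stratified, disjoint, covering and deterministic", {
  subjects <- c(lapply(1:25, function(i) make_rec(label = 1L, id = sprintf("a%02d", i))),
                lapply(1:22, function(i) make_rec(label = 0L, id = sprintf("t%02d", i))))
  sp <- make_splits(subjects, seed = 11L)
  labs <- setNames(vapply(subjects, `[[`, integer(1), "label"),
                   vapply(subjects, `[[`, character(1), "subject_id"))
  expect_length(sp$train_ids, 28L)
  expect_length(sp$val_ids, 10L)
  expect_length(sp$test_ids, 9L)
  expect_identical(sum(labs[sp$train_ids]), 15L)  # 15 ASD + 13 TD
  expect_identical(sum(labs[sp$val_ids]), 5L)     # 5 + 5
  expect_identical(sum(labs[sp$test_ids]), 5L)    # 5 + 4
  # disjoint and covering for any seed
  for (seed in 1:5) {
    s <- make_splits(subjects, seed = seed)
    all_ids <- c(s$train_ids, s$val_ids, s$test_ids)
    expect_identical(sort(all_ids), sort(names(labs)))
    expect_identical(anyDuplicated(all_ids), 0L)
  }
  expect_identical(make_splits(subjects, seed = 3L), make_splits(subjects, seed = 3L))

  even <- c(lapply(1:10, function(i) make_rec(label = 1L, id = paste0("p", i))),
            lapply(1:10, function(i) make_rec(label = 0L, id = paste0("q", i))))
  se <- make_splits(even, seed = 1L)
  expect_length(se$train_ids, 12L)
  expect_length(se$val_ids, 4L)
  expect_length(se$test_ids, 4L)
})

test_that("build_dataset composes selection, windowing and labelling", {
  subjects <- list(make_rec(m = 50L, c = 2L, label = 1L, id = "a", seed = 1),
                   make_rec(m = 50L, c = 2L, label = 0L, id = "b", seed = 2),
                   make_rec(m = 50L, c = 2L, label = 1L, id = "c", seed = 3),
                   make_rec(m = 50L, c = 2L, label = 0L, id = "d", seed = 4),
                   make_rec(m = 50L, c = 2L, label = 1L, id = "e", seed = 5),
                   make_rec(m = 50L, c = 2L, label = 0L, id = "f", seed = 6))
  split <- list(train_ids = c("a", "b"), val_ids = c("c", "d"),
                test_ids = c("e", "f"), seed = 1L)
  cfg <- window_config(30L, 10L)
  ds <- build_dataset(subjects, split, cfg)
  # (50 - 30) / 10 = 2 windows per subject, starts at rows 0 and 10
  expect_identical(dim(ds$train$tensor), c(4L, 30L, 2L, 1L))
  expect_equal(ds$train$tensor[1, , , 1],
               unname(select_attribute(subjects[[1]], "HbO2")[1:30, ]))
  expect_equal(ds$train$tensor[2, , , 1],
               unname(select_attribute(subjects[[1]], "HbO2")[11:40, ]))
  # label fidelity and split hygiene
  expect_identical(ds$train$labels, c(1L, 1L, 0L, 0L))
  expect_length(intersect(ds$train$subject_ids, ds$val$subject_ids), 0L)
  expect_length(intersect(ds$train$subject_ids, ds$test$subject_ids), 0L)

  empty <- build_dataset(subjects,
                         list(train_ids = character(0), val_ids = c("a", "b", "c", "d"),
                              test_ids = c("e", "f")),
                         cfg)
  expect_identical(dim(empty$train$tensor)[1L], 0L)
})

test_that("cohort manifest round-trips", {
  dir <- withr::local_tempdir()
  subjects <- list(make_rec(id = "s1", label = 1L), make_rec(id = "s2", label = 0L))
  man <- write_cohort(subjects, dir)
  back <- read_cohort(man)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, integer(1), "label"), c(1L, 0L))
  expect_equal(back[[1]]$values, subjects[[1]]$values, ignore_attr = TRUE)
})
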