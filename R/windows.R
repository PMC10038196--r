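#' Sliding-window configuration
#'
#' A recording of `m` samples is expanded into `N_i = (m - w) / s` overlapping
#' windows of `w` samples advanced by `s` samples, the count rounded to the
#' nearest integer (`rounding = "nearest"`, the default). With the 0.07-s
#' sampling interval the default `w = 30` gives 2.1-s short time series.
#' Consecutive windows overlap by `w - s` samples.
#'
#' @param window_w Window length in samples (positive integer).
#' @param step_s Step between window starts in samples; must be `< window_w`.
#' @param rounding `"nearest"` (half away from zero) or `"floor"` for the
#'   window-count rule.
#' @return Object of class `"window_config"`.
#' @export
window_config <- function(window_w = 30L, step_s = 10L,
                          rounding = c("nearest", "floor")) {
  if (!is_count(window_w) || window_w < 1) stopf("`window_w` must be a positive integer")
  if (!is_count(step_s) || step_s < 1) stopf("`step_s` must be a positive integer")
  if (step_s >= window_w) stopf("`step_s` must be smaller than `window_w`")
  structure(list(window_w = as.integer(window_w), step_s = as.integer(step_s),
                 rounding = match.arg(rounding)),
            class = "window_config")
}

n_windows <- function(m, cfg) {
  raw <- (m - cfg$window_w) / cfg$step_s
  n <- if (cfg$rounding == "nearest") round_half_up(raw) else floor(raw)
  max(0L, as.integer(n))
}

#' Expand a single-attribute matrix into overlapping windows
#'
#' Window `k` (0-based) covers rows `[k*s, k*s + w)` (half-open). The count
#' follows the configured rounding rule on `(m - w) / s`; no trailing partial
#' window is emitted and the final full window starting at `m - w` is dropped
#' when the rule rounds down past it.
#'
#' @param x Numeric `m x c` matrix (samples x channels).
#' @param cfg A [window_config()].
#' @return 4-D array of dimension `(N_i, w, c, 1)`.
#' @export
slide_windows <- function(x, cfg) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("`x` must be a numeric matrix")
  m <- nrow(x); c <- ncol(x)
  if (m < cfg$window_w) stopf("recording (%d samples) shorter than window (%d)", m, cfg$window_w)
  n <- n_windows(m, cfg)
  out <- array(0, dim = c(n, cfg$window_w, c, 1L))
  for (k in seq_len(n)) {
    start <- (k - 1L) * cfg$step_s
    out[k, , , 1L] <- x[(start + 1L):(start + cfg$window_w), , drop = FALSE]
  }
  out
}

#' Windowed dataset container
#'
#' Bundles the 4-D window tensor `(N, w, c, 1)` with per-window labels and
#' source-subject ids; every window carries the label of the subject it was cut
#' from.
#'
#' @param tensor 4-D numeric array `(N, w, c, 1)`.
#' @param labels Integer vector of 0/1 labels, length `N`.
#' @param subject_ids Character vector, length `N`.
#' @return Object of class `"windowed_dataset"`.
#' @export
windowed_dataset <- function(tensor, labels, subject_ids) {
  if (length(dim(tensor)) != 4L) stopf("`tensor` must be a 4-D array (N, w, c, 1)")
  n <- dim(tensor)[1L]
  if (length(labels) != n || length(subject_ids) != n) {
    stopf("labels and subject_ids must have one entry per window")
  }
  if (n > 0 && !all(labels %in% c(0L, 1L))) stopf("labels must be 0 or 1")
  structure(list(tensor = tensor, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<windowed_dataset> %d windows x %d samples x %d channels (%d subjects; %d labelled 1)\n",
              d[1], d[2], d[3], length(unique(x$subject_ids)), sum(x$labels == 1L)))
  invisible(x)
}

#' Class-stratified subject-level splits
#'
#' Subjects are shuffled within each class (seeded) and allocated to
#' train/validation/test by the given ratios: the training count is the floor
#' of the train ratio, remaining subjects go to validation first (ceiling of
#' its share of the remainder) and then test. For 25 + 22 subjects at 6:2:2
#' this reproduces train 28 (15/13), validation 10 (5/5), test 9 (5/4). Windows
#' never cross splits because the split is by subject.
#'
#' @param subjects List of [subject_recording()] objects.
#' @param ratios Numeric length-3 train/val/test ratios summing to 1.
#' @param seed Integer seed; the split is a pure function of (ids, labels, seed).
#' @return Object of class `"split_spec"`: list with character vectors
#'   `train_ids`, `val_ids`, `test_ids` and the `seed`.
#' @export
make_splits <- function(subjects, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L) {
    stopf("`ratios` must be three numbers summing to 1")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  labels <- vapply(subjects, function(s) s$label, integer(1))
  if (anyDuplicated(ids)) stopf("duplicate subject ids")
  if (length(unique(labels)) < 2L) stopf("both classes must be present to stratify")
  alloc <- list(train = character(0), val = character(0), test = character(0))
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      cls_ids <- sort(ids[labels == cls])
      n <- length(cls_ids)
      if (n < 3L) stopf("class %d has %d subjects; need at least 3 to split", cls, n)
      cls_ids <- sample(cls_ids)
      n_train <- floor(ratios[1] * n)
      rem <- n - n_train
      n_val <- ceiling(rem * ratios[2] / (ratios[2] + ratios[3]))
      alloc$train <- c(alloc$train, cls_ids[seq_len(n_train)])
      alloc$val <- c(alloc$val, cls_ids[n_train + seq_len(n_val)])
      alloc$test <- c(alloc$test, cls_ids[(n_train + n_val + 1):n])
    }
  })
  structure(list(train_ids = alloc$train, val_ids = alloc$val,
                 test_ids = alloc$test, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> train %d / val %d / test %d subjects (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids), x$seed))
  invisible(x)
}

window_one_subject <- function(rec, cfg, attribute, region) {
  x <- select_attribute(rec, attribute)
  x <- subset_region(x, region)
  slide_windows(x, cfg)
}

#' Build windowed train/validation/test datasets from a cohort
#'
#' Composes attribute selection, region subsetting and sliding-window
#' expansion per subject, replicating each subject's label over its windows.
#'
#' @param subjects List of [subject_recording()] objects.
#' @param split A [make_splits()] result covering the subjects.
#' @param cfg A [window_config()].
#' @param attribute Hemoglobin attribute to model (default `"HbO2"`).
#' @param region Region name, [region_spec()] or channel vector (default whole).
#' @return Named list of three [windowed_dataset()]s: `train`, `val`, `test`.
#' @export
build_dataset <- function(subjects, split, cfg = window_config(),
                          attribute = "HbO2", region = "whole") {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  all_split <- c(split$train_ids, split$val_ids, split$test_ids)
  missing <- setdiff(all_split, ids)
  if (length(missing)) stopf("split references unknown subjects: %s",
                             paste(missing, collapse = ", "))
  build_one <- function(want_ids) {
    keep <- subjects[match(want_ids, ids)]
    if (length(keep) == 0L) {
      c0 <- if (identical(region, "whole")) subjects[[1L]]$n_channels
            else if (is.character(region)) length(region_spec(region)$channels)
            else if (inherits(region, "region_spec")) length(region$channels)
            else length(region)
      return(windowed_dataset(array(0, c(0L, cfg$window_w, c0, 1L)),
                              integer(0), character(0)))
    }
    parts <- lapply(keep, window_one_subject, cfg = cfg,
                    attribute = attribute, region = region)
    counts <- vapply(parts, function(p) dim(p)[1L], integer(1))
    total <- sum(counts)
    cdim <- dim(parts[[1L]])[3L]
    tensor <- array(0, dim = c(total, cfg$window_w, cdim, 1L))
    at <- 0L
    for (p in parts) {
      n <- dim(p)[1L]
      if (n > 0) tensor[at + seq_len(n), , , ] <- p
      at <- at + n
    }
    windowed_dataset(tensor,
                     labels = rep(vapply(keep, function(s) s$label, integer(1)), counts),
                     subject_ids = rep(want_ids, counts))
  }
  list(train = build_one(split$train_ids),
       val = build_one(split$val_ids),
       test = build_one(split$test_ids))
}
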