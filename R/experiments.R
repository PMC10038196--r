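#' Experiment grids over window length, attribute or region
#'
#' Re-runs the full pipeline (windowing, training with early stopping,
#' test-set evaluation) while varying exactly one axis and holding the
#' subject-level splits, seed and every other setting fixed:
#'
#' * `axis = "window"`: sliding-window lengths (default 20, 30, 50 samples,
#'   i.e. 1.4 s, 2.1 s and 3.5 s at the 0.07-s sampling interval);
#' * `axis = "attribute"`: hemoglobin attribute (default HbO2 vs Hb; HbT is
#'   excluded as it is not independent);
#' * `axis = "region"`: cortical regions (default the six lobe/hemisphere
#'   regions).
#'
#' @param subjects Cohort: list of [subject_recording()]s.
#' @param axis Which axis to vary.
#' @param levels Optional axis levels overriding the defaults above
#'   (window lengths in samples, attribute names, or region names).
#' @param split Optional [make_splits()] result; computed from `seed` if
#'   missing.
#' @param window_w,step_s Base window configuration for the axes that do not
#'   vary it.
#' @param attribute,region Base attribute and region for the other axes.
#' @param threshold Decision threshold for the reported metrics.
#' @param seed Seed shared by all grid cells.
#' @param ... Passed to [asgcn()] (architecture and training settings).
#' @return Data frame with one row per grid cell: the varied level, window
#'   duration in seconds, accuracy, precision, sensitivity, specificity and
#'   AUC (full-sweep).
#' @export
run_experiment_grid <- function(subjects,
                                axis = c("window", "attribute", "region"),
                                levels = NULL, split = NULL,
                                window_w = 30L, step_s = 10L,
                                attribute = "HbO2", region = "whole",
                                threshold = 0.5, seed = 1L, ...) {
  axis <- match.arg(axis)
  if (is.null(levels)) {
    levels <- switch(axis,
                     window = c(20L, 30L, 50L),
                     attribute = c("HbO2", "Hb"),
                     region = region_names())
  }
  if (is.null(split)) split <- make_splits(subjects, seed = seed)
  dt <- subjects[[1L]]$sampling_interval_s
  rows <- lapply(levels, function(lv) {
    w <- window_w; att <- attribute; reg <- region
    if (axis == "window") w <- as.integer(lv)
    if (axis == "attribute") att <- lv
    if (axis == "region") reg <- lv
    ds <- build_dataset(subjects, split, window_config(w, step_s),
                        attribute = att, region = reg)
    fit <- asgcn(ds$train, ds$val, seed = seed, keep_fitted = FALSE, ...)
    ev <- asgcn_evaluate(fit, ds$test, threshold = threshold)
    data.frame(level = as.character(lv),
               window_s = w * dt,
               accuracy = ev$metrics$accuracy,
               precision = ev$metrics$precision,
               sensitivity = ev$metrics$sensitivity,
               specificity = ev$metrics$specificity,
               auc = if (is.null(ev$roc)) NA_real_ else ev$roc$auc,
               n_train_windows = dim(ds$train$tensor)[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- axis
  rownames(out) <- NULL
  out
}
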