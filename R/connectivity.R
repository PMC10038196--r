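#' Channel pairs with strong learned correlation in the 44-channel montage
#'
#' The eleven frontotemporal channel pairs reported as strongly correlated in
#' the learned whole-brain adjacency for this montage, shipped as the default
#' pair set for the edge-deletion ablation workflow. Channels are 1-based.
#'
#' @return Integer matrix with columns `i`, `j` (i < j), one row per pair.
#' @export
strong_pairs_44 <- function() {
  m <- rbind(c(3, 5), c(3, 9), c(5, 9), c(4, 23), c(17, 26), c(1, 28),
             c(22, 32), c(10, 34), c(1, 40), c(15, 41), c(3, 44))
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j")
  m
}

#' Extract the learned adjacency matrix from a fitted model
#'
#' Returns the adaptive adjacency computed from the fitted node embedding
#' (with the model's training-time edge mask applied, if any). The raw
#' row-softmax matrix is generally asymmetric; for reporting it is
#' symmetrized as `(A + t(A)) / 2` by default.
#'
#' @param model Fitted [asgcn()] (or [asgcn_model()]) object.
#' @param symmetrize Return the symmetrized matrix (default `TRUE`).
#' @param file Optional CSV path; the matrix is written with channel headers
#'   `ch1..chN`.
#' @param heatmap Optional PNG path for a heatmap with 0-based axis labels.
#' @return `N x N` numeric matrix.
#' @export
extract_adjacency <- function(model, symmetrize = TRUE, file = NULL,
                              heatmap = NULL) {
  if (is.null(model$params$E)) stopf("model has no node embedding; not initialized")
  a <- adaptive_adjacency(model$params$E, model$mask)
  if (isTRUE(symmetrize)) a <- (a + t(a)) / 2
  dimnames(a) <- list(paste0("ch", seq_len(nrow(a))), paste0("ch", seq_len(nrow(a))))
  if (!is.null(file)) {
    utils::write.csv(as.data.frame(a), file, row.names = TRUE)
  }
  if (!is.null(heatmap)) {
    grDevices::png(heatmap, width = 720, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    n <- nrow(a)
    graphics::image(0:(n - 1), 0:(n - 1), t(a), xlab = "channel (0-based)",
                    ylab = "channel (0-based)", main = "learned adjacency")
  }
  a
}

#' Strongest off-diagonal edges of an adjacency matrix
#'
#' Excludes the diagonal (channel autocorrelation), deduplicates symmetric
#' entries (using the mean of the two directions when the matrix is
#' asymmetric), and returns the top-`k` pairs or all pairs above `threshold`,
#' sorted by descending weight with ties broken by lexicographic channel
#' order.
#'
#' @param adjacency Square non-negative matrix (or a fitted [asgcn()] model).
#' @param k Number of pairs to return; mutually exclusive with `threshold`.
#' @param threshold Minimum weight.
#' @return Object of class `"edge_report"`: data frame with 1-based columns
#'   `i`, `j` (i < j) and `weight`.
#' @export
top_edges <- function(adjacency, k = NULL, threshold = NULL) {
  if (inherits(adjacency, "asgcn_model")) {
    adjacency <- extract_adjacency(adjacency, symmetrize = TRUE)
  }
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stopf("`adjacency` must be a square matrix")
  }
  if (any(adjacency < 0)) stopf("`adjacency` must be non-negative")
  if (!is.null(k) && k < 0) stopf("`k` must be non-negative")
  n <- nrow(adjacency)
  sym <- (adjacency + t(adjacency)) / 2
  idx <- which(upper.tri(sym), arr.ind = TRUE)
  rep_df <- data.frame(i = idx[, 1L], j = idx[, 2L], weight = sym[idx])
  rep_df <- rep_df[order(-rep_df$weight, rep_df$i, rep_df$j), , drop = FALSE]
  if (!is.null(threshold)) rep_df <- rep_df[rep_df$weight >= threshold, , drop = FALSE]
  if (!is.null(k)) rep_df <- utils::head(rep_df, k)
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("edge_report", "data.frame"))
}

#' Edge-deletion ablation
#'
#' Measures each listed channel pair's contribution to classification by
#' retraining the model with that pair's adjacency entries clamped to zero at
#' every forward pass (both symmetric entries; no renormalization), alongside
#' an unmasked baseline. Test-set accuracy/sensitivity/specificity are
#' recorded at every epoch after a burn-in, yielding a distribution per
#' condition (the data behind ablation boxplots). All conditions share the
#' same seed, architecture and training configuration.
#'
#' @param train,val,test [windowed_dataset()]s.
#' @param pairs List (or two-column matrix) of unordered 1-based channel
#'   pairs to delete, one condition per pair.
#' @param burn_in Epochs discarded from the start of each run (default 5).
#' @param mode `"retrain"` (default) retrains under each mask;
#'   `"inference"` trains one baseline model and only masks at evaluation
#'   time (cheaper, but measures a different quantity).
#' @param seed Seed shared by every condition.
#' @param ... Passed to [asgcn()] (architecture and training settings).
#' @return Object of class `"ablation_result"`: long-format data frame with
#'   columns `condition` (`"All"` for the baseline or `"Delete i-j"`),
#'   `epoch`, `metric`, `value`.
#' @export
edge_ablation <- function(train, val, test, pairs = strong_pairs_44(),
                          burn_in = 5L, mode = c("retrain", "inference"),
                          seed = 1L, ...) {
  mode <- match.arg(mode)
  n_nodes <- dim(train$tensor)[3L]
  pairs <- normalize_pairs(pairs, n_nodes)
  conditions <- c(list(NULL),
                  lapply(seq_len(nrow(pairs)), function(i) pairs[i, , drop = FALSE]))
  names(conditions) <- c("All",
                         if (nrow(pairs)) sprintf("Delete %d-%d", pairs[, 1L], pairs[, 2L]))
  base_fit <- NULL
  rows <- lapply(names(conditions), function(cond) {
    msk <- conditions[[cond]]
    if (mode == "retrain" || is.null(msk)) {
      fit <- asgcn(train, val, seed = seed, mask = msk, eval_data = test,
                   keep_fitted = FALSE, ...)
      if (is.null(msk)) base_fit <<- fit
      h <- fit$history
    } else {
      # inference-only: evaluate the baseline model under the mask, per epoch
      # snapshot is unavailable, so report the final model's masked metrics.
      ev <- dataset_loss(base_fit$params, base_fit$config, test, msk)
      cc <- confusion_counts(test$labels, as.integer(ev$p >= 0.5))
      met <- suppressWarnings(classification_metrics(cc))
      h <- data.frame(epoch = base_fit$best_epoch,
                      eval_accuracy = met$accuracy,
                      eval_sensitivity = met$sensitivity,
                      eval_specificity = met$specificity)
    }
    h <- h[h$epoch > burn_in | nrow(h) <= burn_in, , drop = FALSE]
    do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity"), function(mname) {
      data.frame(condition = cond, epoch = h$epoch, metric = mname,
                 value = h[[paste0("eval_", mname)]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("ablation_result", "data.frame"))
}

#' @export
plot.ablation_result <- function(x, metric = "accuracy", ...) {
  sub <- x[x$metric == metric, , drop = FALSE]
  sub$condition <- factor(sub$condition, levels = unique(x$condition))
  graphics::boxplot(value ~ condition, data = sub, las = 2,
                    ylab = metric, xlab = "", ...)
  invisible(x)
}
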