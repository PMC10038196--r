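adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Mean BCE + probabilities over a dataset, evaluated in batches.
dataset_loss <- function(params, cfg, data, mask, batch_size = 256L) {
  n <- dim(data$tensor)[1L]
  p <- numeric(n)
  loss <- 0
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    sub <- data$tensor[idx, , , , drop = FALSE]
    fw <- forward_batch(params, cfg, batch_to_steps(sub, cfg), B = length(idx),
                        mask = mask, keep = FALSE)
    p[idx] <- fw$p
    loss <- loss + bce_from_logits(fw$logits, data$labels[idx]) * length(idx)
  }
  list(loss = loss / n, p = p)
}

#' Fit an adaptive spatiotemporal graph convolutional classifier
#'
#' Trains the network on windowed fNIRS data with Adam, minimizing binary
#' cross-entropy, evaluating the validation loss each epoch and stopping early
#' when it has not improved for `patience` epochs (or at `max_epochs`). The
#' parameters of the best-validation-loss epoch are restored. No learning-rate
#' or weight decay is applied.
#'
#' @param train,val [windowed_dataset()]s; `val` drives early stopping (if
#'   `NULL`, training runs for `max_epochs` epochs).
#' @param hidden,n_layers,embed_dim,in_features,normalize_input Architecture,
#'   see [asgcn_config()].
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Windows per gradient step (default 64).
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience on validation loss (default 15).
#' @param seed Integer seed covering initialization and shuffling.
#' @param mask Optional edge mask (two-column matrix of 1-based node pairs)
#'   applied to the learned adjacency at every forward pass; used by the
#'   edge-deletion ablation.
#' @param eval_data Optional extra [windowed_dataset()] (e.g. the test set)
#'   whose accuracy/sensitivity/specificity are recorded every epoch in the
#'   history - the data behind ablation boxplots. Never used for model
#'   selection.
#' @param keep_fitted If `TRUE` (default), store best-model scores for the
#'   training set (used by [residuals.asgcn()]).
#' @param verbose Print one line per epoch.
#' @return Object of class `"asgcn"` (extending `"asgcn_model"`): list with
#'   `params`, `config`, `mask`, `history` (one row per epoch), `best_epoch`,
#'   `val_scores`, and the matched call.
#' @seealso [predict.asgcn()], [asgcn_evaluate()], [extract_adjacency()]
#' @export
asgcn <- function(train, val = NULL, hidden = 64L, n_layers = 2L,
                  embed_dim = 7L, in_features = 1L, normalize_input = FALSE,
                  lr = 0.001, batch_size = 64L, max_epochs = 100L,
                  patience = 15L, seed = 1L, mask = NULL, eval_data = NULL,
                  keep_fitted = TRUE, verbose = FALSE) {
  if (!inherits(train, "windowed_dataset")) stopf("`train` must be a windowed_dataset")
  n_train <- dim(train$tensor)[1L]
  if (n_train < 1L) stopf("empty training set")
  if (length(unique(train$labels)) < 2L) {
    stopf("training set contains a single class; both labels are required")
  }
  if (!is.null(val) && dim(val$tensor)[1L] < 1L) stopf("empty validation set")
  if (lr <= 0) stopf("`lr` must be positive")
  if (patience >= max_epochs) stopf("`patience` must be smaller than `max_epochs`")
  cfg <- asgcn_config(n_nodes = dim(train$tensor)[3L], hidden = hidden,
                      n_layers = n_layers, embed_dim = embed_dim,
                      in_features = in_features,
                      normalize_input = normalize_input)
  model <- asgcn_model(cfg, seed = seed)
  params <- model$params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  since_best <- 0L
  history <- list()
  mask_pairs <- if (!is.null(mask)) normalize_pairs(mask, cfg$n_nodes) else NULL

  epoch_order <- with_seed(seed, {
    lapply(seq_len(max_epochs), function(e) sample.int(n_train))
  })

  aborted <- FALSE
  for (epoch in seq_len(max_epochs)) {
    ord <- epoch_order[[epoch]]
    tr_loss <- 0
    for (at in seq(1L, n_train, by = batch_size)) {
      idx <- ord[at:min(at + batch_size - 1L, n_train)]
      sub <- train$tensor[idx, , , , drop = FALSE]
      res <- asgcn_loss_grad(params, cfg, batch_to_steps(sub, cfg),
                             train$labels[idx], B = length(idx),
                             mask = mask_pairs)
      if (!is.finite(res$loss)) {
        warning("non-finite training loss; keeping last good parameters",
                call. = FALSE)
        theta <- best$theta
        params <- unflatten_params(theta, model$params)
        aborted <- TRUE
        break
      }
      step <- adam_step(theta, flatten_params(res$grads), opt, lr)
      theta <- step$theta
      opt <- step$state
      params <- unflatten_params(theta, model$params)
      tr_loss <- tr_loss + res$loss * length(idx)
    }
    row <- list(epoch = epoch, train_loss = tr_loss / n_train,
                val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      vl <- dataset_loss(params, cfg, val, mask_pairs)
      row$val_loss <- vl$loss
      row$val_acc <- mean((vl$p >= 0.5) == (val$labels == 1L))
      if (vl$loss < best$loss - 1e-12) {
        best <- list(loss = vl$loss, theta = theta, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
    } else {
      best <- list(loss = row$train_loss, theta = theta, epoch = epoch)
    }
    if (!is.null(eval_data)) {
      ev <- dataset_loss(params, cfg, eval_data, mask_pairs)
      cc <- confusion_counts(eval_data$labels, as.integer(ev$p >= 0.5))
      met <- suppressWarnings(classification_metrics(cc))
      row$eval_accuracy <- met$accuracy
      row$eval_sensitivity <- met$sensitivity
      row$eval_specificity <- met$specificity
    }
    history[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, row$train_loss,
                      if (is.na(row$val_loss)) "-" else sprintf("%.4f (acc %.3f)", row$val_loss, row$val_acc)))
    }
    if (aborted) break
    if (!is.null(val) && since_best >= patience) break
  }

  params <- unflatten_params(best$theta, model$params)
  history <- do.call(rbind, lapply(history, function(r) as.data.frame(r)))
  val_scores <- if (!is.null(val)) dataset_loss(params, cfg, val, mask_pairs)$p else NULL
  train_scores <- if (isTRUE(keep_fitted)) dataset_loss(params, cfg, train, mask_pairs)$p else NULL
  structure(list(config = cfg, params = params,
                 mask = mask_pairs, history = history,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 n_train = n_train, train_labels = train$labels,
                 fitted_scores = train_scores,
                 val_labels = if (!is.null(val)) val$labels else NULL,
                 val_scores = val_scores,
                 seed = as.integer(seed), call = match.call()),
            class = c("asgcn", "asgcn_model"))
}

#' Predict class probabilities or labels for windowed data
#'
#' @param object A fitted [asgcn()] model (or an initialized [asgcn_model()]).
#' @param newdata A [windowed_dataset()] or 4-D `(B, w, N, 1)` array.
#' @param type `"prob"` for scores, `"class"` for 0/1 labels.
#' @param threshold Decision threshold; label 1 iff score `>= threshold`.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 labels with the
#'   scores in attribute `"scores"`.
#' @export
predict.asgcn <- function(object, newdata, type = c("prob", "class"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  tensor <- if (inherits(newdata, "windowed_dataset")) newdata$tensor else newdata
  if (dim(tensor)[3L] != object$config$n_nodes) {
    stopf("data has %d nodes but the model expects %d",
          dim(tensor)[3L], object$config$n_nodes)
  }
  p <- dataset_loss(object$params, object$config,
                    list(tensor = tensor, labels = integer(dim(tensor)[1L])),
                    object$mask)$p
  if (type == "prob") return(p)
  structure(as.integer(p >= threshold), scores = p)
}

#' @export
predict.asgcn_model <- predict.asgcn

#' @export
print.asgcn <- function(x, ...) {
  cat(sprintf("Adaptive spatiotemporal graph convolutional classifier\n"))
  cat(sprintf("  nodes %d, layers %d, hidden %d, embedding dim %d\n",
              x$config$n_nodes, x$config$n_layers, x$config$hidden,
              x$config$embed_dim))
  cat(sprintf("  trained %d epoch(s); best epoch %d (val loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              if (is.finite(x$best_val_loss)) x$best_val_loss else NA))
  if (!is.null(x$mask) && nrow(x$mask)) {
    cat(sprintf("  %d adjacency edge(s) masked\n", nrow(x$mask)))
  }
  invisible(x)
}

#' @export
summary.asgcn <- function(object, threshold = 0.5, ...) {
  out <- list(config = object$config, best_epoch = object$best_epoch,
              n_epochs = nrow(object$history),
              n_parameters = length(flatten_params(object$params)),
              best_val_loss = object$best_val_loss)
  if (!is.null(object$val_scores)) {
    cc <- confusion_counts(object$val_labels,
                           as.integer(object$val_scores >= threshold))
    out$val_confusion <- cc
    out$val_metrics <- suppressWarnings(classification_metrics(cc))
  }
  structure(out, class = "summary.asgcn")
}

#' @export
print.summary.asgcn <- function(x, ...) {
  cat(sprintf("ASGCN fit: %d parameters, best epoch %d of %d\n",
              x$n_parameters, x$best_epoch, x$n_epochs))
  if (!is.null(x$val_metrics)) {
    m <- x$val_metrics
    cat(sprintf("Validation: accuracy %.3f  sensitivity %.3f  specificity %.3f  precision %.3f\n",
                m$accuracy, m$sensitivity, m$specificity, m$precision))
  }
  invisible(x)
}

#' @export
coef.asgcn <- function(object, component = c("all", "embedding", "adjacency"),
                       ...) {
  component <- match.arg(component)
  switch(component,
         all = object$params,
         embedding = object$params$E,
         adjacency = adaptive_adjacency(object$params$E, object$mask))
}

#' @export
residuals.asgcn <- function(object, ...) {
  if (is.null(object$fitted_scores)) {
    stopf("model was fitted with keep_fitted = FALSE; no stored scores")
  }
  object$train_labels - object$fitted_scores
}

#' Plot a fitted model: training history or learned adjacency
#'
#' @param x A fitted [asgcn()] object.
#' @param type `"history"` for loss curves, `"adjacency"` for a heatmap of the
#'   (symmetrized) learned adjacency with 0-based axis labels.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.asgcn <- function(x, type = c("history", "adjacency"), ...) {
  type <- match.arg(type)
  if (type == "history") {
    h <- x$history
    ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
    plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
         ylim = ylim, ...)
    if (any(!is.na(h$val_loss))) {
      graphics::lines(h$epoch, h$val_loss, lty = 2)
      graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
    }
    graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  } else {
    a <- extract_adjacency(x, symmetrize = TRUE)
    n <- nrow(a)
    graphics::image(0:(n - 1), 0:(n - 1), t(a[n:1, , drop = FALSE]),
                    xlab = "channel (0-based)", ylab = "channel (0-based)",
                    axes = FALSE, ...)
    graphics::axis(1, at = pretty(0:(n - 1)))
    graphics::axis(2, at = pretty(0:(n - 1)), labels = rev(pretty(0:(n - 1))))
  }
  invisible(x)
}
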