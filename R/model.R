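#' Adaptive adjacency from a node embedding
#'
#' The learned graph is `A = row_softmax(ReLU(E %*% t(E)))` for a node
#' embedding `E` (N x d). Softmax normalizes each row to sum to 1 (computed
#' with per-row max subtraction for stability). An optional edge mask zeroes
#' listed symmetric entries *after* normalization, without renormalizing:
#' deleting an edge sets its correlation to 0 and leaves all other entries
#' untouched.
#'
#' @param E Numeric `N x d` node-embedding matrix.
#' @param mask Optional two-column matrix (or list of pairs) of unordered
#'   1-based node pairs to zero.
#' @return `N x N` non-negative matrix; rows sum to 1 before masking.
#' @examples
#' adaptive_adjacency(matrix(0, 3, 2))  # every row = 1/3
#' @export
adaptive_adjacency <- function(E, mask = NULL) {
  if (!is.matrix(E) || !is.numeric(E)) stopf("`E` must be a numeric matrix")
  if (any(!is.finite(E))) stopf("`E` contains non-finite values")
  s <- E %*% t(E)
  a <- row_softmax(pmax(s, 0))
  if (!is.null(mask)) {
    pairs <- normalize_pairs(mask, nrow(E))
    if (nrow(pairs)) {
      a[pairs] <- 0
      a[pairs[, 2:1, drop = FALSE]] <- 0
    }
  }
  a
}

row_softmax <- function(x) {
  x <- exp(x - apply(x, 1L, max))
  x / rowSums(x)
}

# --- internal batched layout -------------------------------------------------
# Activations for a batch of B windows are (B*N) x C matrices with rows
# node-fastest: row (b-1)*N + i is node i of window b. Graph propagation then
# reduces to one N x (B*C) matrix product via column-major reshaping.

gmul <- function(P, x, N, B) {
  matrix(P %*% matrix(x, N, B * ncol(x)), N * B, ncol(x))
}

rep_rows <- function(v, B) rep.int(v, B)

sigm <- function(x) 1 / (1 + exp(-x))

# NWAL forward on an already-propagated input M = P %*% U.
# W: d x C x H pool array; bm: d x H bias pool; per-node weights are
# W_i = sum_k E[i,k] W[k,,], b_i = E[i,] %*% bm. The embedding contraction is
# evaluated as T = M %*% [W_1 | ... | W_d] followed by an embedding-weighted
# sum of the d output blocks, so each gate costs one BLAS call per step.
nwal_core <- function(M, E, erep, W, bm, B) {
  N <- nrow(E); d <- dim(W)[1L]; H <- dim(W)[3L]
  gc <- list(W2 = pool_cbind(W),
             bias_rep = (E %*% bm)[rep(seq_len(N), B), , drop = FALSE])
  gate_fwd(M, gc, erep, d, H)
}

gate_fwd <- function(M, gate_ctx, erep, d, H) {
  tm <- M %*% gate_ctx$W2
  out <- gate_ctx$bias_rep
  for (k in seq_len(d)) {
    out <- out + tm[, (k - 1L) * H + seq_len(H), drop = FALSE] * erep[, k]
  }
  out
}

# cbind(W[1,,], ..., W[d,,]): C x (d*H); and the (d*H) x C stack of t(W_k).
pool_cbind <- function(W) {
  d <- dim(W)[1L]; C <- dim(W)[2L]; H <- dim(W)[3L]
  matrix(aperm(W, c(2L, 3L, 1L)), C, d * H)
}

pool_cbind_t <- function(W) {
  d <- dim(W)[1L]; C <- dim(W)[2L]; H <- dim(W)[3L]
  matrix(aperm(W, c(3L, 1L, 2L)), d * H, C)
}

# Inverse of pool_cbind on an accumulated gradient matrix.
pool_uncbind <- function(Wf, d, C, H) {
  aperm(array(Wf, dim = c(C, H, d)), c(3L, 1L, 2L))
}

# Per-batch precomputation shared by every step: adjacency, replicated
# embedding, and per-gate flattened pools and replicated biases.
make_ctx <- function(params, cfg, B, mask) {
  N <- cfg$n_nodes
  s <- params$E %*% t(params$E)
  a0 <- row_softmax(pmax(s, 0))
  a <- a0
  pairs <- if (!is.null(mask)) normalize_pairs(mask, N) else matrix(integer(0), ncol = 2L)
  if (nrow(pairs)) {
    a[pairs] <- 0
    a[pairs[, 2:1, drop = FALSE]] <- 0
  }
  P <- diag(N) + a
  rep_idx <- rep(seq_len(N), B)
  list(S = s, A0 = a0, pairs = pairs, P = P, tP = t(P),
       erep = params$E[rep_idx, , drop = FALSE], grp = rep_idx,
       layers = lapply(params$layers, function(lay) {
         lapply(lay, function(g) {
           list(W2 = pool_cbind(g$W), W2t = pool_cbind_t(g$W),
                bias_rep = (params$E %*% g$b)[rep_idx, , drop = FALSE])
         })
       }))
}

#' Node-weight-adaptive graph convolution
#'
#' One graph-convolution layer whose per-node weights are generated from a
#' shared low-rank weight pool: `Z_i = ((I + A) X)_i W_i + b_i` with
#' `W_i = sum_k E[i,k] W_pool[k,,]` and `b_i = E[i,] b_pool`. When all rows of
#' `E` are identical this reduces to an ordinary shared-weight first-order
#' graph convolution.
#'
#' @param X Numeric `N x C_in` node-feature matrix.
#' @param adj `N x N` adjacency (e.g. from [adaptive_adjacency()]); the
#'   propagation matrix used is `I + adj`.
#' @param E Node embedding `N x d`.
#' @param pool List with `W` (`d x C_in x C_out` array) and `b` (`d x C_out`
#'   matrix).
#' @return `N x C_out` matrix.
#' @export
nwal_gcn <- function(X, adj, E, pool) {
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(E)
  if (nrow(X) != N || nrow(adj) != N || ncol(adj) != N) {
    stopf("X, adj and E disagree on the number of nodes")
  }
  if (dim(pool$W)[2L] != ncol(X)) {
    stopf("pool expects %d input features, got %d", dim(pool$W)[2L], ncol(X))
  }
  P <- diag(N) + adj
  nwal_core(P %*% X, E, E, pool$W, pool$b, B = 1L)
}

#' One step of the graph-convolutional GRU
#'
#' A GRU cell whose gate transformations are node-weight-adaptive graph
#' convolutions over the concatenated `[h_prev, X_t]` features:
#' `z = sigmoid(G_z([h, x]))`, `r = sigmoid(G_r([h, x]))`,
#' `hhat = tanh(G_h([r * h, x]))`, `h' = (1 - z) * h + z * hhat`.
#'
#' @param X_t `N x C_in` input at one time step.
#' @param h_prev `N x H` previous hidden state.
#' @param params List with elements `z`, `r`, `h`, each a pool as in
#'   [nwal_gcn()] over `C_in + H` input features.
#' @param adj Adjacency matrix as in [nwal_gcn()].
#' @param E Shared node embedding.
#' @return `N x H` new hidden state.
#' @export
gcgru_step <- function(X_t, h_prev, params, adj, E) {
  if (!is.matrix(X_t)) X_t <- as.matrix(X_t)
  u <- cbind(h_prev, X_t)
  z <- stats::plogis(nwal_gcn(u, adj, E, params$z))
  r <- stats::plogis(nwal_gcn(u, adj, E, params$r))
  hhat <- tanh(nwal_gcn(cbind(r * h_prev, X_t), adj, E, params$h))
  (1 - z) * h_prev + z * hhat
}

#' Network architecture configuration
#'
#' @param n_nodes Number of channels/graph nodes.
#' @param hidden Hidden units per node (default 64).
#' @param n_layers Stacked encoder layers (default 2).
#' @param embed_dim Node-embedding dimension `d` (default 7; intended
#'   `d << n_nodes`).
#' @param in_features Input features per node per time step (default 1).
#' @param normalize_input If `TRUE`, z-score each window before encoding
#'   (default off).
#' @return Object of class `"asgcn_config"`.
#' @export
asgcn_config <- function(n_nodes, hidden = 64L, n_layers = 2L, embed_dim = 7L,
                         in_features = 1L, normalize_input = FALSE) {
  for (v in c(n_nodes, hidden, n_layers, embed_dim, in_features)) {
    if (!is_count(v) || v < 1) stopf("architecture sizes must be positive integers")
  }
  structure(list(n_nodes = as.integer(n_nodes), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), embed_dim = as.integer(embed_dim),
                 in_features = as.integer(in_features),
                 normalize_input = isTRUE(normalize_input)),
            class = "asgcn_config")
}

# Pools are contracted with the node embedding (variance ~ 1/d per entry), so
# a Glorot-style bound on the *effective* per-node weight keeps gate
# pre-activations O(1): Var(W_eff) = d * Var(E) * Var(pool) = Var(pool).
new_pool <- function(d, c_in, h) {
  a <- sqrt(6 / (c_in + h))
  list(W = array(stats::runif(d * c_in * h, -a, a), dim = c(d, c_in, h)),
       b = matrix(0, d, h))
}

#' Initialize network parameters
#'
#' All gate pools and the adjacency share one node-embedding matrix `E`;
#' embeddings and pools are drawn from small fan-in-scaled uniform
#' distributions.
#'
#' @param config An [asgcn_config()].
#' @param seed Integer seed.
#' @return Object of class `"asgcn_model"`: list with the `config` and a
#'   `params` list (`E`, per-layer gate pools, decoder weights).
#' @export
asgcn_model <- function(config, seed = 1L) {
  with_seed(seed, {
    N <- config$n_nodes; H <- config$hidden; d <- config$embed_dim
    layers <- lapply(seq_len(config$n_layers), function(l) {
      c_in <- if (l == 1L) config$in_features else H
      list(z = new_pool(d, H + c_in, H),
           r = new_pool(d, H + c_in, H),
           h = new_pool(d, H + c_in, H))
    })
    b_e <- sqrt(3 / d)  # unit-variance embedding rows
    params <- list(
      E = matrix(stats::runif(N * d, -b_e, b_e), N, d),
      layers = layers,
      dec = list(conv_w = stats::runif(H, -1, 1) * sqrt(3 / H), conv_b = 0,
                 fc_w = stats::runif(N, -1, 1) * sqrt(3 / N), fc_b = 0)
    )
    structure(list(config = config, params = params), class = "asgcn_model")
  })
}

#' @export
print.asgcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<asgcn_model> %d nodes, %d layers, hidden %d, embed dim %d (%d parameters)\n",
              cfg$n_nodes, cfg$n_layers, cfg$hidden, cfg$embed_dim,
              length(flatten_params(x$params))))
  invisible(x)
}

#' Encode one window through the stacked recurrent encoder
#'
#' Layer 1 consumes the window step by step from zero initial state; each
#' deeper layer consumes the previous layer's hidden sequence. The final time
#' step's hidden state of the last layer is returned (final-state readout).
#'
#' @param window `w x N x C_in` array (a `w x N` matrix is promoted).
#' @param model An [asgcn_model()] (or the fitted object from [asgcn()]).
#' @param mask Optional edge mask as in [adaptive_adjacency()].
#' @return `N x hidden` matrix.
#' @export
encode_sequence <- function(window, model, mask = NULL) {
  cfg <- model$config; p <- model$params
  if (is.matrix(window)) window <- array(window, dim = c(dim(window), 1L))
  if (length(dim(window)) != 3L || dim(window)[1L] < 1L) {
    stopf("`window` must be a non-empty w x N x C array")
  }
  w <- dim(window)[1L]
  xt <- lapply(seq_len(w), function(t) matrix(window[t, , ], cfg$n_nodes, cfg$in_features))
  fw <- forward_batch(p, cfg, xt, B = 1L, mask = mask, keep = FALSE)
  fw$h_last
}

#' Decode a hidden state to a class probability
#'
#' A 1x1 convolution collapses the hidden feature axis to one value per node;
#' a fully connected layer collapses nodes to a single logit; a sigmoid yields
#' `P(label = 1)`.
#'
#' @param hidden `N x hidden` matrix (the [encode_sequence()] output).
#' @param dec Decoder parameters: list with `conv_w` (length `hidden`),
#'   `conv_b`, `fc_w` (length `N`), `fc_b`.
#' @return Probability strictly in (0, 1).
#' @export
decode <- function(hidden, dec) {
  if (length(dec$conv_w) != ncol(hidden) || length(dec$fc_w) != nrow(hidden)) {
    stopf("decoder dimensions do not match the hidden state")
  }
  v <- hidden %*% dec$conv_w + dec$conv_b
  stats::plogis(sum(dec$fc_w * v) + dec$fc_b)
}

#' Forward pass over a batch of windows
#'
#' @param batch 4-D array `(B, w, N, 1)` as produced by the windowing
#'   pipeline, or a [windowed_dataset()].
#' @param model An [asgcn_model()] or fitted [asgcn()] object.
#' @param mask Optional edge mask.
#' @return Numeric vector of `B` probabilities, batch order preserved.
#' @export
asgcn_forward <- function(batch, model, mask = NULL) {
  if (inherits(batch, "windowed_dataset")) batch <- batch$tensor
  if (length(dim(batch)) != 4L) stopf("`batch` must be a 4-D (B, w, N, 1) array")
  cfg <- model$config
  if (dim(batch)[3L] != cfg$n_nodes) {
    stopf("batch has %d nodes but the model expects %d", dim(batch)[3L], cfg$n_nodes)
  }
  fw <- forward_batch(model$params, cfg, batch_to_steps(batch, cfg), B = dim(batch)[1L],
                      mask = mask, keep = FALSE)
  fw$p
}

# Convert (B, w, N, 1) tensor into a list over time of (B*N) x C matrices
# (node-fastest rows), optionally z-scoring each window first.
batch_to_steps <- function(batch, cfg) {
  B <- dim(batch)[1L]; w <- dim(batch)[2L]; N <- dim(batch)[3L]
  if (isTRUE(cfg$normalize_input) && B > 0) {
    for (b in seq_len(B)) {
      x <- batch[b, , , ]
      batch[b, , , ] <- (x - mean(x)) / max(stats::sd(x), 1e-8)
    }
  }
  lapply(seq_len(w), function(t) {
    matrix(t(matrix(batch[, t, , 1L], B, N)), B * N, 1L)
  })
}

# Full forward pass. xt: list over time of (B*N) x C_in matrices.
# Returns probabilities, logits and (optionally) all caches for backprop.
forward_batch <- function(params, cfg, xt, B, mask = NULL, keep = TRUE,
                          ctx = NULL) {
  N <- cfg$n_nodes; H <- cfg$hidden; d <- cfg$embed_dim
  w <- length(xt)
  if (w < 1L) stopf("empty window")
  if (is.null(ctx)) ctx <- make_ctx(params, cfg, B, mask)
  P <- ctx$P; erep <- ctx$erep
  cache <- if (keep) list(ctx = ctx, xt = xt,
                          layers = vector("list", cfg$n_layers))
           else NULL
  seq_in <- xt
  for (l in seq_len(cfg$n_layers)) {
    lctx <- ctx$layers[[l]]
    h <- matrix(0, B * N, H)
    steps <- if (keep) vector("list", w) else NULL
    out_seq <- vector("list", w)
    for (t in seq_len(w)) {
      u <- cbind(h, seq_in[[t]])
      mu <- gmul(P, u, N, B)
      z <- sigm(gate_fwd(mu, lctx$z, erep, d, H))
      r <- sigm(gate_fwd(mu, lctx$r, erep, d, H))
      u2 <- cbind(r * h, seq_in[[t]])
      mu2 <- gmul(P, u2, N, B)
      hhat <- tanh(gate_fwd(mu2, lctx$h, erep, d, H))
      h_new <- (1 - z) * h + z * hhat
      if (keep) steps[[t]] <- list(u = u, mu = mu, u2 = u2, mu2 = mu2,
                                   z = z, r = r, hhat = hhat, h_prev = h)
      h <- h_new
      out_seq[[t]] <- h
    }
    if (keep) cache$layers[[l]] <- steps
    seq_in <- out_seq
  }
  h_last <- seq_in[[w]]
  v <- h_last %*% params$dec$conv_w + params$dec$conv_b
  vmat <- matrix(v, N, B)
  logits <- as.vector(crossprod(vmat, params$dec$fc_w)) + params$dec$fc_b
  p <- stats::plogis(logits)
  if (keep) {
    cache$h_last <- h_last
    cache$B <- B
  }
  list(p = p, logits = logits,
       h_last = matrix(h_last[seq_len(N), , drop = FALSE], N, H),
       cache = cache)
}
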