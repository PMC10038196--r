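# Independent oracles and small fixtures used across the suite.

# Straightforward dense first-order graph convolution with one shared weight:
# Z = (I + A) X W + b. Deliberately written without reusing package internals.
dense_gcn_oracle <- function(X, A, W, b) {
  Z <- (diag(nrow(A)) + A) %*% X %*% W
  sweep(Z, 2L, b, "+")
}

tiny_model <- function(n_nodes = 4L, hidden = 3L, n_layers = 2L,
                       embed_dim = 2L, seed = 7L) {
  asgcn_model(asgcn_config(n_nodes = n_nodes, hidden = hidden,
                           n_layers = n_layers, embed_dim = embed_dim),
              seed = seed)
}

# A small two-class cohort with disjoint planted graphs and a fast enough
# oscillation band that a single short window shows the coupling.
quick_cohort <- function(n_per_class = 4L, m = 400L, n_channels = 6L,
                         edges_asd = rbind(c(1L, 2L)),
                         edges_td = rbind(c(3L, 4L)),
                         coupling = 0.6, seed = 1L) {
  cohort_config(n_asd = n_per_class, n_td = n_per_class, m = m,
                n_channels = n_channels,
                graph_asd = planted_graph(n_channels, edges_asd, coupling),
                graph_td = planted_graph(n_channels, edges_td, coupling),
                osc_band_hz = c(0.1, 0.7), noise_sd = 0.3, seed = seed)
}

# Central finite difference of the batch loss along one flat parameter index.
numeric_grad_entry <- function(model, xt, y, B, idx, eps = 1e-6, mask = NULL) {
  theta <- asgcn:::flatten_params(model$params)
  shifted <- function(delta) {
    th <- theta
    th[idx] <- th[idx] + delta
    p <- asgcn:::unflatten_params(th, model$params)
    fw <- asgcn:::forward_batch(p, model$config, xt, B = B, mask = mask,
                                keep = FALSE)
    asgcn:::bce_from_logits(fw$logits, y)
  }
  (shifted(eps) - shifted(-eps)) / (2 * eps)
}
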