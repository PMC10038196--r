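# The network core: adaptive adjacency, node-weight-adaptive graph
# convolution, the graph-convolutional GRU cell, encoder and decoder.

test_that("adaptive adjacency is the row-softmax of ReLU(E E^T)", {
  # all-zero embedding: ReLU(0) = 0, softmax of a zero row is uniform
  expect_equal(adaptive_adjacency(matrix(0, 3, 2)),
               matrix(1 / 3, 3, 3))
  # 2x2 identity embedding: each row softmax(c(1, 0)) in diagonal-first order
  a <- adaptive_adjacency(diag(2))
  e <- exp(1)
  expect_equal(a, matrix(c(e, 1, 1, e) / (e + 1), 2, 2), tolerance = 1e-12)
  expect_error(adaptive_adjacency(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("rows are stochastic before masking, over random embeddings", {
  set.seed(123)
  for (i in 1:100) {
    E <- matrix(rnorm(6 * 3), 6, 3)
    a <- adaptive_adjacency(E)
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, 6), tolerance = 1e-6)
  }
})

test_that("edge masks zero both symmetric entries and touch nothing else", {
  set.seed(5)
  E <- matrix(rnorm(5 * 2), 5, 2)
  a <- adaptive_adjacency(E)
  am <- adaptive_adjacency(E, mask = rbind(c(1L, 2L)))
  expect_identical(am[1, 2], 0)
  expect_identical(am[2, 1], 0)
  keep <- !(row(a) %in% 1:2 & col(a) %in% 1:2 & row(a) != col(a))
  expect_identical(am[keep], a[keep])  # bitwise unchanged elsewhere
})

test_that("NWAL reduces to known closed forms", {
  set.seed(2)
  N <- 3L; d <- 2L; C <- 2L; H <- 4L
  E <- matrix(rnorm(N * d), N, d)
  adj <- adaptive_adjacency(E)
  X <- matrix(rnorm(N * C), N, C)
  # zero weight pool: output is the per-node bias E[i,] %*% b_pool, X-free
  pool0 <- list(W = array(0, c(d, C, H)), b = matrix(rnorm(d * H), d, H))
  z0 <- nwal_gcn(X, adj, E, pool0)
  expect_equal(z0, E %*% pool0$b, ignore_attr = TRUE)
  expect_equal(z0, nwal_gcn(X * 10, adj, E, pool0))
  # single node with unit self-weight: I + A doubles the input
  E1 <- matrix(1, 1, 1)
  pool1 <- list(W = array(0.5, c(1, 1, 1)), b = matrix(0.25, 1, 1))
  z1 <- nwal_gcn(matrix(3), matrix(1, 1, 1), E1, pool1)
  expect_equal(as.numeric(z1), 2 * 3 * 0.5 + 0.25)
})

test_that("identical embedding rows reproduce the shared-weight convolution", {
  set.seed(8)
  N <- 6L; d <- 3L; C <- 2L; H <- 5L
  e_row <- rnorm(d)
  E <- matrix(e_row, N, d, byrow = TRUE)
  pool <- list(W = array(rnorm(d * C * H), c(d, C, H)),
               b = matrix(rnorm(d * H), d, H))
  X <- matrix(rnorm(N * C), N, C)
  adj <- adaptive_adjacency(matrix(rnorm(N * 2), N, 2))
  # shared weight implied by the degenerate embedding
  W_shared <- matrix(0, C, H)
  for (k in seq_len(d)) W_shared <- W_shared + e_row[k] * pool$W[k, , ]
  b_shared <- as.numeric(e_row %*% pool$b)
  expect_lt(max(abs(nwal_gcn(X, adj, E, pool) -
                    dense_gcn_oracle(X, adj, W_shared, b_shared))), 1e-6)
})

test_that("the GCGRU cell has the zero-parameter closed form and is bounded", {
  N <- 4L; H <- 3L; C <- 1L; d <- 2L
  E <- matrix(rnorm(N * d), N, d)
  adj <- adaptive_adjacency(E)
  zero_pool <- function(c_in) list(W = array(0, c(d, c_in, H)),
                                   b = matrix(0, d, H))
  params0 <- list(z = zero_pool(H + C), r = zero_pool(H + C), h = zero_pool(H + C))
  h_prev <- matrix(rnorm(N * H), N, H)
  x <- matrix(rnorm(N * C), N, C)
  # zero pools: z = r = 1/2, hhat = 0, so h' = h/2
  expect_equal(gcgru_step(x, h_prev, params0, adj, E), 0.5 * h_prev)
  expect_equal(gcgru_step(x, matrix(0, N, H), params0, adj, E),
               matrix(0, N, H))
  # h' is an entrywise convex combination of h_prev and tanh output
  set.seed(77)
  for (i in 1:100) {
    rp <- function(c_in) list(W = array(rnorm(d * c_in * H), c(d, c_in, H)),
                              b = matrix(rnorm(d * H), d, H))
    pars <- list(z = rp(H + C), r = rp(H + C), h = rp(H + C))
    h_in <- matrix(runif(N * H, -1, 1), N, H)
    h_out <- gcgru_step(matrix(rnorm(N * C), N, C), h_in, pars, adj, E)
    expect_true(all(h_out >= -1 & h_out <= 1))
  }
})

test_that("encoder composes layers and produces the documented shape", {
  mod <- tiny_model(n_nodes = 4L, hidden = 3L, n_layers = 2L, embed_dim = 2L)
  # zero window with zero parameters stays at zero
  mod0 <- mod
  mod0$params <- asgcn:::zero_like(mod$params)
  out0 <- encode_sequence(array(0, c(5L, 4L, 1L)), mod0)
  expect_equal(out0, matrix(0, 4L, 3L))
  # w = 1 equals one cell step per layer, manually composed
  x1 <- matrix(rnorm(4), 4, 1)
  adj <- adaptive_adjacency(mod$params$E)
  h1 <- gcgru_step(x1, matrix(0, 4, 3), mod$params$layers[[1]], adj, mod$params$E)
  h2 <- gcgru_step(h1, matrix(0, 4, 3), mod$params$layers[[2]], adj, mod$params$E)
  expect_equal(encode_sequence(array(x1, c(1L, 4L, 1L)), mod), h2,
               tolerance = 1e-12)
  # default montage-scale configuration: hidden state is 44 x 64
  big <- asgcn_model(asgcn_config(n_nodes = 44L), seed = 1L)
  win <- array(rnorm(30 * 44), c(30L, 44L, 1L))
  expect_identical(dim(encode_sequence(win, big)), c(44L, 64L))
  expect_error(encode_sequence(array(0, c(0L, 4L, 1L)), mod), "non-empty")
})

test_that("decoder maps hidden states to probabilities in (0, 1)", {
  set.seed(4)
  dec <- list(conv_w = rnorm(3), conv_b = 0.1, fc_w = rnorm(4), fc_b = -0.2)
  hid <- matrix(rnorm(12), 4, 3)
  p <- decode(hid, dec)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_identical(decode(hid, dec), p)  # deterministic
  dec0 <- list(conv_w = rep(0, 3), conv_b = 0, fc_w = rep(0, 4), fc_b = 0)
  expect_equal(decode(matrix(0, 4, 3), dec0), 0.5)
  expect_error(decode(hid, list(conv_w = 1, conv_b = 0, fc_w = 1, fc_b = 0)),
               "dimensions")
})

test_that("batched forward equals the per-window loop and preserves order", {
  mod <- tiny_model(n_nodes = 4L, hidden = 3L)
  set.seed(9)
  batch <- array(rnorm(6 * 5 * 4), c(6L, 5L, 4L, 1L))
  p <- asgcn_forward(batch, mod)
  expect_length(p, 6L)
  loop <- vapply(1:6, function(b) {
    decode(encode_sequence(batch[b, , , , drop = TRUE], mod), mod$params$dec)
  }, numeric(1))
  expect_equal(p, loop, tolerance = 1e-12)
  # duplicated window, duplicated output
  batch2 <- batch
  batch2[2, , , ] <- batch2[1, , , ]
  p2 <- asgcn_forward(batch2, mod)
  expect_identical(p2[1], p2[2])
  expect_error(asgcn_forward(array(0, c(2, 5, 7, 1)), mod), "expects")
})

test_that("adjacency and gate weights share one embedding matrix", {
  mod <- tiny_model()
  set.seed(10)
  x <- matrix(rnorm(4), 4, 1)
  adj_before <- adaptive_adjacency(mod$params$E)
  gate_before <- nwal_gcn(cbind(matrix(0, 4, 3), x), adj_before, mod$params$E,
                          mod$params$layers[[1]]$z)
  mod$params$E[1, 1] <- mod$params$E[1, 1] + 1
  adj_after <- adaptive_adjacency(mod$params$E)
  gate_after <- nwal_gcn(cbind(matrix(0, 4, 3), x), adj_after, mod$params$E,
                         mod$params$layers[[1]]$z)
  expect_false(identical(adj_before, adj_after))
  expect_false(identical(gate_before, gate_after))
})
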