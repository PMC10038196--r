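# Analytic gradients: full backpropagation through the decoder, the stacked
# graph-convolutional GRU (through time), the node-weight pools, and the
# row-softmax/ReLU adjacency back into the shared node embedding. Verified
# against finite differences in the test suite.

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skel) {
  i <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- vec[i + seq_len(n)]
    i <<- i + n
    attributes(out) <- attributes(s)
    out
  }
  walk(skel)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# Numerically stable mean binary cross-entropy from logits.
bce_from_logits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# Backward through one NWAL call. dZ: gradient at the pre-activation output,
# M = P %*% U (cached), gc the per-gate context (flattened pools, replicated
# bias). Mirrors the forward algebra: with T = M %*% [W_1|...|W_d],
#   out = bias + sum_k e_k * T_k, so
#   dW2 = M' [e_1*dZ | ... | e_d*dZ],  dM = [e_k*dZ]_k %*% rbind(t(W_k)),
#   dE[,k] = per-node sums of <dZ, T_k>,  db = E' Dnode.
# dW2 is left in flattened C x (d*H) form; the caller accumulates and
# reshapes once per batch.
nwal_backward <- function(dZ, M, U, E, gc, ctx, B) {
  N <- nrow(E); d <- ncol(E)
  C <- ncol(M); H <- ncol(dZ)
  nr <- nrow(dZ)
  tm <- M %*% gc$W2
  dT <- matrix(0, nr, d * H)
  dEn <- matrix(0, nr, d)
  for (k in seq_len(d)) {
    blk <- (k - 1L) * H + seq_len(H)
    dZk <- dZ * ctx$erep[, k]
    dT[, blk] <- dZk
    dEn[, k] <- .rowSums(dZ * tm[, blk, drop = FALSE], nr, H)
  }
  Dnode <- rowsum(dZ, ctx$grp)
  dM <- dT %*% gc$W2t
  list(dW2 = crossprod(M, dT),
       db = crossprod(E, Dnode),
       dE = rowsum(dEn, ctx$grp),
       dbias_node = Dnode,
       dU = gmul(ctx$tP, dM, N, B),
       dP = matrix(dM, N, B * C) %*% t(matrix(U, N, B * C)))
}

# Loss + gradients for one batch. xt: list over time of (B*N) x C_in inputs.
asgcn_loss_grad <- function(params, cfg, xt, y, B, mask = NULL) {
  fw <- forward_batch(params, cfg, xt, B = B, mask = mask, keep = TRUE)
  cache <- fw$cache
  ctx <- cache$ctx
  N <- cfg$n_nodes; H <- cfg$hidden; d <- cfg$embed_dim
  w <- length(xt)
  g <- zero_like(params)
  # flattened per-gate pool-gradient accumulators, reshaped once at the end
  gW2 <- lapply(params$layers, function(lay) {
    lapply(lay, function(gate) matrix(0, dim(gate$W)[2L], d * H))
  })
  dP_acc <- matrix(0, N, N)

  dlogits <- (fw$p - y) / B
  h_last <- cache$h_last
  v <- h_last %*% params$dec$conv_w + params$dec$conv_b
  vmat <- matrix(v, N, B)
  g$dec$fc_b <- sum(dlogits)
  g$dec$fc_w <- as.vector(vmat %*% dlogits)
  dv <- as.vector(params$dec$fc_w %o% dlogits)
  g$dec$conv_w <- as.vector(crossprod(h_last, dv))
  g$dec$conv_b <- sum(dv)
  dh_top <- matrix(dv) %*% t(params$dec$conv_w)

  # external per-step gradients injected into the top layer's outputs
  zero_h <- matrix(0, B * N, H)
  dh_ext <- rep(list(zero_h), w)
  dh_ext[[w]] <- dh_top

  for (l in rev(seq_len(cfg$n_layers))) {
    lay <- params$layers[[l]]
    lctx <- ctx$layers[[l]]
    steps <- cache$layers[[l]]
    c_in <- if (l == 1L) cfg$in_features else H
    in_cols <- H + seq_len(c_in)
    dx_list <- vector("list", w)
    dh <- zero_h
    for (t in rev(seq_len(w))) {
      dh <- dh + dh_ext[[t]]
      st <- steps[[t]]
      dz <- dh * (st$hhat - st$h_prev)
      dhhat <- dh * st$z
      dh_prev <- dh * (1 - st$z)

      nb <- nwal_backward(dhhat * (1 - st$hhat^2), st$mu2, st$u2,
                          params$E, lctx$h, ctx, B)
      gW2[[l]]$h <- gW2[[l]]$h + nb$dW2
      g$layers[[l]]$h$b <- g$layers[[l]]$h$b + nb$db
      g$E <- g$E + nb$dE + nb$dbias_node %*% t(lay$h$b)
      dP_acc <- dP_acc + nb$dP
      dr <- nb$dU[, seq_len(H), drop = FALSE] * st$h_prev
      dh_prev <- dh_prev + nb$dU[, seq_len(H), drop = FALSE] * st$r
      dx <- nb$dU[, in_cols, drop = FALSE]

      nbz <- nwal_backward(dz * st$z * (1 - st$z), st$mu, st$u,
                           params$E, lctx$z, ctx, B)
      nbr <- nwal_backward(dr * st$r * (1 - st$r), st$mu, st$u,
                           params$E, lctx$r, ctx, B)
      gW2[[l]]$z <- gW2[[l]]$z + nbz$dW2
      gW2[[l]]$r <- gW2[[l]]$r + nbr$dW2
      g$layers[[l]]$z$b <- g$layers[[l]]$z$b + nbz$db
      g$layers[[l]]$r$b <- g$layers[[l]]$r$b + nbr$db
      g$E <- g$E + nbz$dE + nbz$dbias_node %*% t(lay$z$b) +
                   nbr$dE + nbr$dbias_node %*% t(lay$r$b)
      dP_acc <- dP_acc + nbz$dP + nbr$dP
      du <- nbz$dU + nbr$dU
      dh_prev <- dh_prev + du[, seq_len(H), drop = FALSE]
      dx <- dx + du[, in_cols, drop = FALSE]

      dx_list[[t]] <- dx
      dh <- dh_prev
    }
    dh_ext <- dx_list  # becomes the output gradient of the layer below
  }

  for (l in seq_len(cfg$n_layers)) {
    for (gate in c("z", "r", "h")) {
      C <- dim(params$layers[[l]][[gate]]$W)[2L]
      g$layers[[l]][[gate]]$W <- pool_uncbind(gW2[[l]][[gate]], d, C, H)
    }
  }

  # adjacency: P = I + A, A = masked row-softmax of ReLU(E E^T)
  dA <- dP_acc
  if (nrow(ctx$pairs)) {
    dA[ctx$pairs] <- 0
    dA[ctx$pairs[, 2:1, drop = FALSE]] <- 0
  }
  a0 <- ctx$A0
  dR <- a0 * (dA - rowSums(dA * a0))
  dS <- dR * (ctx$S > 0)
  g$E <- g$E + (dS + t(dS)) %*% params$E

  list(loss = bce_from_logits(fw$logits, y), grads = g, p = fw$p)
}
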