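# Recurrent head: representation -> two stacked bidirectional LSTM layers;
# the final features of BOTH layers (forward state at the last real token,
# backward state at the first token, per layer) are concatenated before the
# dense output stage. Per-label sigmoid scores by default; a softmax
# inference activation is available as a compatibility flag for single-label
# reading of the scores.

rnn_init_params <- function(d, h, Q) {
  l1f <- lstm_init(d, h); l1b <- lstm_init(d, h)
  l2f <- lstm_init(2 * h, h); l2b <- lstm_init(2 * h, h)
  list(
    W1f = l1f$W, U1f = l1f$U, b1f = l1f$b,
    W1b = l1b$W, U1b = l1b$U, b1b = l1b$b,
    W2f = l2f$W, U2f = l2f$U, b2f = l2f$b,
    W2b = l2b$W, U2b = l2b$U, b2b = l2b$b,
    Wo = glorot_uniform(4 * h, Q),
    bo = rep(0, Q)
  )
}

# Split a (B*T) x d flat representation into a list over t of B x d matrices.
flat_to_steps <- function(X, B, T_) {
  lapply(seq_len(T_), function(t) {
    X[(seq_len(B) - 1L) * T_ + t, , drop = FALSE]
  })
}

rnn_forward_pass <- function(fit, ids, n_tokens, keep_cache = FALSE) {
  p <- fit$params; h <- fit$hyper$rnn_hidden
  B <- nrow(ids); T_ <- ncol(ids)
  idx <- as.vector(t(ids))
  Xf <- represent_batch(ids, n_tokens, embeddings = p$emb, pe = fit$pe,
                        use_embedding = fit$spec$use_embedding,
                        use_positional = fit$spec$use_positional, d = fit$d)
  X <- flat_to_steps(Xf, B, T_)
  at <- pmin(pmax(n_tokens, 1L), T_)
  f1f <- lstm_dir_forward(X, p$W1f, p$U1f, p$b1f, reverse = FALSE)
  f1b <- lstm_dir_forward(X, p$W1b, p$U1b, p$b1b, reverse = TRUE)
  H1 <- lapply(seq_len(T_), function(t) cbind(f1f$H[[t]], f1b$H[[t]]))
  f2f <- lstm_dir_forward(H1, p$W2f, p$U2f, p$b2f, reverse = FALSE)
  f2b <- lstm_dir_forward(H1, p$W2b, p$U2b, p$b2b, reverse = TRUE)
  feat <- cbind(gather_timestep(f1f$H, at), f1b$H[[1]],
                gather_timestep(f2f$H, at), f2b$H[[1]])
  logits <- feat %*% p$Wo + matrix(p$bo, B, length(fit$label_space),
                                   byrow = TRUE)
  out <- list(logits = logits)
  if (keep_cache) {
    out$cache <- list(X = X, H1 = H1, f1f = f1f, f1b = f1b, f2f = f2f,
                      f2b = f2b, feat = feat, at = at, idx = idx,
                      B = B, T_ = T_)
  }
  out
}

rnn_backward_pass <- function(fit, cache, dlogits) {
  p <- fit$params; h <- fit$hyper$rnn_hidden
  B <- cache$B; T_ <- cache$T_
  grads <- list()
  grads$Wo <- crossprod(cache$feat, dlogits)
  grads$bo <- colSums(dlogits)
  dfeat <- dlogits %*% t(p$Wo)
  sl <- function(j) (j - 1L) * h + seq_len(h)
  # layer-2 features
  dH2f <- zero_like_list(cache$f2f$H)
  dH2f <- scatter_timestep(dH2f, dfeat[, sl(3), drop = FALSE], cache$at)
  dH2b <- zero_like_list(cache$f2b$H)
  dH2b[[1]] <- dH2b[[1]] + dfeat[, sl(4), drop = FALSE]
  b2f <- lstm_dir_backward(dH2f, cache$f2f, cache$H1, p$W2f, p$U2f)
  b2b <- lstm_dir_backward(dH2b, cache$f2b, cache$H1, p$W2b, p$U2b)
  grads$W2f <- b2f$dW; grads$U2f <- b2f$dU; grads$b2f <- b2f$db
  grads$W2b <- b2b$dW; grads$U2b <- b2b$dU; grads$b2b <- b2b$db
  # layer-1: gradient from layer 2 inputs plus the layer-1 feature slice
  dH1f <- vector("list", T_); dH1b <- vector("list", T_)
  for (t in seq_len(T_)) {
    dh1 <- b2f$dX[[t]] + b2b$dX[[t]]
    dH1f[[t]] <- dh1[, seq_len(h), drop = FALSE]
    dH1b[[t]] <- dh1[, h + seq_len(h), drop = FALSE]
  }
  dH1f <- scatter_timestep(dH1f, dfeat[, sl(1), drop = FALSE], cache$at)
  dH1b[[1]] <- dH1b[[1]] + dfeat[, sl(2), drop = FALSE]
  b1f <- lstm_dir_backward(dH1f, cache$f1f, cache$X, p$W1f, p$U1f)
  b1b <- lstm_dir_backward(dH1b, cache$f1b, cache$X, p$W1b, p$U1b)
  grads$W1f <- b1f$dW; grads$U1f <- b1f$dU; grads$b1f <- b1f$db
  grads$W1b <- b1b$dW; grads$U1b <- b1b$dU; grads$b1b <- b1b$db
  if (fit$spec$use_embedding && fit$spec$trainable) {
    dXf <- matrix(0, B * T_, fit$d)
    for (t in seq_len(T_)) {
      dXf[(seq_len(B) - 1L) * T_ + t, ] <- b1f$dX[[t]] + b1b$dX[[t]]
    }
    grads$emb <- embedding_grad(dXf, cache$idx, nrow(p$emb), fit$d)
  }
  grads
}
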