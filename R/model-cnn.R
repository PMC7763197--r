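# Convolutional head: representation -> 1-D valid convolution (width 3,
# stride 1, ReLU) -> global max pool per filter -> concatenation with the
# mean-pooled embedding features -> dense(ReLU) -> dense -> sigmoid.
# The global max pool deliberately destroys position, which is exactly why
# fusing the sinusoidal positional encoding into the embeddings matters.

cnn_init_params <- function(d, n_filters, hidden, Q, conv_width = 3L) {
  list(
    Wc = glorot_uniform(conv_width * d, n_filters),
    bc = rep(0, n_filters),
    W1 = glorot_uniform(n_filters + d, hidden),
    b1 = rep(0, hidden),
    W2 = glorot_uniform(hidden, Q),
    b2 = rep(0, Q)
  )
}

#' Convolutional feature extraction over a represented sequence
#'
#' Valid 1-D convolution of width `conv_width` (default 3) and stride 1 over
#' the token axis, followed by a rectifier: position `i` emits
#' `relu(window_i . u + b)` per filter, where `window_i` stacks the
#' `conv_width` consecutive d-dimensional slot vectors.
#'
#' @param sequence_matrix A `max_len x d` representation matrix.
#' @param weights A `(conv_width * d) x n_filters` filter matrix.
#' @param bias Per-filter bias vector.
#' @param conv_width Filter width in token slots.
#' @return A `(max_len - conv_width + 1) x n_filters` feature matrix.
#' @export
conv_feature <- function(sequence_matrix, weights, bias = 0,
                         conv_width = 3L) {
  X <- as.matrix(sequence_matrix)
  T_ <- nrow(X); d <- ncol(X)
  if (T_ < conv_width) {
    abort(paste0("max_len = ", T_, " is shorter than the filter width ",
                 conv_width))
  }
  if (nrow(weights) != conv_width * d) {
    abort("`weights` must have conv_width * d rows")
  }
  P <- T_ - conv_width + 1L
  U <- do.call(cbind, lapply(seq_len(conv_width) - 1L, function(o) {
    X[seq_len(P) + o, , drop = FALSE]
  }))
  relu(U %*% weights + matrix(bias, P, ncol(weights), byrow = TRUE))
}

# Forward pass over an encoded batch. Returns logits plus the caches needed
# for the backward pass.
cnn_forward_pass <- function(fit, ids, n_tokens, keep_cache = FALSE) {
  p <- fit$params; hp <- fit$hyper
  B <- nrow(ids); T_ <- ncol(ids); d <- fit$d
  kc <- hp$conv_width
  if (T_ < kc) abort("max_len shorter than the convolution width")
  P <- T_ - kc + 1L
  idx <- as.vector(t(ids))
  X <- represent_batch(ids, n_tokens, embeddings = p$emb, pe = fit$pe,
                       use_embedding = fit$spec$use_embedding,
                       use_positional = fit$spec$use_positional, d = d)
  rows1 <- rep((seq_len(B) - 1L) * T_, each = P) + rep(seq_len(P), B)
  U <- do.call(cbind, lapply(seq_len(kc) - 1L, function(o) {
    X[rows1 + o, , drop = FALSE]
  }))
  Hlin <- U %*% p$Wc + matrix(p$bc, B * P, hp$n_filters, byrow = TRUE)
  Hr <- relu(Hlin)
  H3 <- array(Hr, c(P, B, hp$n_filters))
  pooled <- H3[1, , , drop = FALSE]
  dim(pooled) <- c(B, hp$n_filters)
  amax <- matrix(1L, B, hp$n_filters)
  if (P > 1) {
    for (j in 2:P) {
      layer <- H3[j, , , drop = FALSE]
      dim(layer) <- c(B, hp$n_filters)
      better <- layer > pooled
      pooled[better] <- layer[better]
      amax[better] <- j
    }
  }
  M <- rowsum(X, rep(seq_len(B), each = T_)) / n_tokens
  Z <- cbind(pooled, M)
  A1lin <- Z %*% p$W1 + matrix(p$b1, B, hp$hidden, byrow = TRUE)
  A1 <- relu(A1lin)
  logits <- A1 %*% p$W2 + matrix(p$b2, B, length(fit$label_space),
                                 byrow = TRUE)
  out <- list(logits = logits)
  if (keep_cache) {
    out$cache <- list(X = X, idx = idx, U = U, rows1 = rows1,
                      relu_conv = Hlin > 0, amax = amax, Z = Z,
                      A1 = A1, relu_1 = A1lin > 0, n_tokens = n_tokens,
                      B = B, T_ = T_, P = P)
  }
  out
}

cnn_backward_pass <- function(fit, cache, dlogits) {
  p <- fit$params; hp <- fit$hyper
  B <- cache$B; T_ <- cache$T_; P <- cache$P
  d <- fit$d; Fn <- hp$n_filters; kc <- hp$conv_width
  grads <- list()
  grads$W2 <- crossprod(cache$A1, dlogits)
  grads$b2 <- colSums(dlogits)
  dA1 <- (dlogits %*% t(p$W2)) * cache$relu_1
  grads$W1 <- crossprod(cache$Z, dA1)
  grads$b1 <- colSums(dA1)
  dZ <- dA1 %*% t(p$W1)
  dpooled <- dZ[, seq_len(Fn), drop = FALSE]
  dM <- dZ[, Fn + seq_len(d), drop = FALSE]
  # route the pooled gradient to the argmax conv position of each filter
  dHr <- matrix(0, B * P, Fn)
  rows <- as.vector((seq_len(B) - 1L) * P + cache$amax)
  cols <- rep(seq_len(Fn), each = B)
  dHr[cbind(rows, cols)] <- dHr[cbind(rows, cols)] + as.vector(dpooled)
  dHlin <- dHr * cache$relu_conv
  grads$Wc <- crossprod(cache$U, dHlin)
  grads$bc <- colSums(dHlin)
  dU <- dHlin %*% t(p$Wc)
  dX <- matrix(0, B * T_, d)
  for (o in seq_len(kc) - 1L) {
    dX[cache$rows1 + o, ] <- dX[cache$rows1 + o, , drop = FALSE] +
      dU[, o * d + seq_len(d), drop = FALSE]
  }
  dX <- dX + dM[rep(seq_len(B), each = T_), , drop = FALSE] /
    cache$n_tokens[rep(seq_len(B), each = T_)]
  if (fit$spec$use_embedding && fit$spec$trainable) {
    grads$emb <- embedding_grad(dX, cache$idx, nrow(p$emb), d)
  }
  grads
}

# Scatter-add per-slot gradients into embedding rows; the padding row (ID 0)
# never updates.
embedding_grad <- function(dX, idx, n_rows, d) {
  rs <- rowsum(dX, idx)
  gemb <- matrix(0, n_rows, d)
  rid <- as.integer(rownames(rs)) + 1L
  keep <- rid != 1L
  gemb[rid[keep], ] <- rs[keep, , drop = FALSE]
  gemb
}
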