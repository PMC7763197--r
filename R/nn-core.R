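# Vectorized neural-network primitives: parameter initialization, the ADAM
# update, binary cross-entropy on logits, and a bidirectional LSTM with full
# backpropagation through time. Everything operates on plain matrices so a
# batch step is a handful of BLAS calls; gradients are checked against finite
# differences in the test suite.

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) plogis(x)

# Numerically stable mean binary cross-entropy computed from logits.
bce_from_logits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# d loss / d logits for the mean BCE above.
bce_grad <- function(logits, y) {
  (sigmoid(logits) - y) / length(logits)
}

# --- ADAM -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- LSTM -------------------------------------------------------------------

# Gate order in the stacked weight matrices: input, forget, output, cell.
lstm_init <- function(d_in, h) {
  lim <- 1 / sqrt(h)
  W <- matrix(runif(d_in * 4 * h, -lim, lim), d_in, 4 * h)
  U <- matrix(runif(h * 4 * h, -lim, lim), h, 4 * h)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  list(W = W, U = U, b = b)
}

# One direction over a batch. X: list over t = 1..T of B x d_in matrices.
# reverse = TRUE processes t = T..1. Returns hidden states per t plus the
# caches BPTT needs.
lstm_dir_forward <- function(X, W, U, b, reverse = FALSE) {
  T_ <- length(X); B <- nrow(X[[1]]); h <- nrow(U)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h_prev <- matrix(0, B, h); c_prev <- matrix(0, B, h)
  H <- vector("list", T_); cache <- vector("list", T_)
  for (t in steps) {
    A <- X[[t]] %*% W + h_prev %*% U + matrix(b, B, 4 * h, byrow = TRUE)
    i <- sigmoid(A[, 1:h, drop = FALSE])
    f <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
    o <- sigmoid(A[, (2 * h + 1):(3 * h), drop = FALSE])
    g <- tanh(A[, (3 * h + 1):(4 * h), drop = FALSE])
    c_cur <- f * c_prev + i * g
    tc <- tanh(c_cur)
    h_cur <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
    H[[t]] <- h_cur
    h_prev <- h_cur; c_prev <- c_cur
  }
  list(H = H, cache = cache, steps = steps)
}

# BPTT for one direction. dH: list over t of B x h gradients w.r.t. the
# emitted hidden states (zeros where unused). Returns weight gradients and
# the gradient w.r.t. the inputs X.
lstm_dir_backward <- function(dH, fwd, X, W, U) {
  T_ <- length(X); B <- nrow(X[[1]]); h <- nrow(U)
  dW <- W * 0; dU <- U * 0; db <- rep(0, 4 * h)
  dX <- lapply(X, function(x) x * 0)
  dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
  for (t in rev(fwd$steps)) {
    cc <- fwd$cache[[t]]
    dh <- dH[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW <- dW + crossprod(X[[t]], dA)
    dU <- dU + crossprod(cc$h_prev, dA)
    db <- db + colSums(dA)
    dX[[t]] <- dX[[t]] + dA %*% t(W)
    dh_next <- dA %*% t(U)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# Gather one row per sequence from a list of per-timestep matrices:
# out[b, ] = H[[at[b]]][b, ].
gather_timestep <- function(H, at) {
  B <- length(at)
  out <- matrix(0, B, ncol(H[[1]]))
  for (t in unique(at)) {
    rows <- which(at == t)
    out[rows, ] <- H[[t]][rows, , drop = FALSE]
  }
  out
}

# Scatter the feature gradient back: dH[[at[b]]][b, ] += dF[b, ].
scatter_timestep <- function(dH, dF, at) {
  for (t in unique(at)) {
    rows <- which(at == t)
    dH[[t]][rows, ] <- dH[[t]][rows, , drop = FALSE] + dF[rows, , drop = FALSE]
  }
  dH
}

zero_like_list <- function(X) lapply(X, function(x) x * 0)
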