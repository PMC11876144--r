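# Shared machinery for the neural branches: parameter initialisation,
# softmax cross-entropy, and the Adam optimiser. Parameters, gradients and
# optimiser moments are flat named lists of matrices/vectors.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# row-wise softmax with the usual max-shift for stability
softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / .rowSums(E, nrow(E), ncol(E))
}

# mean cross-entropy of integer labels (1-based) and its logit gradient
softmax_xent <- function(logits, y1) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  py <- P[cbind(seq_len(n), y1)]
  loss <- -mean(log(pmax(py, 1e-12)))
  dlogits <- P
  dlogits[cbind(seq_len(n), y1)] <- dlogits[cbind(seq_len(n), y1)] - 1
  list(loss = loss, dlogits = dlogits / n, P = P)
}

adam_new <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# minibatch index blocks after a seeded shuffle
batch_blocks <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

check_deep_xy <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_talsrx("X rows must match length of y")
  if (any(!y %in% 0:10)) stop_talsrx("y must hold class indices 0..10")
  X
}
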