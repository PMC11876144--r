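#' Configuration of the ANN-LSTM branch
#'
#' The hybrid network passes the 192 plate features through a dense ReLU
#' layer of 128 hidden units, feeds that embedding as a length-one sequence
#' into an LSTM cell with 128 units, and maps the LSTM output to the eleven
#' class logits. Training minimises cross-entropy with Adam. Defaults are
#' the reference configuration (`lr = 0.01`, `epochs = 500`); epochs can be
#' reduced for quick runs.
#'
#' @param ann_hidden dense-layer width.
#' @param lstm_hidden LSTM cell width.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @return an `ann_lstm_config` list.
#' @export
ann_lstm_config <- function(ann_hidden = 128L, lstm_hidden = 128L,
                            lr = 0.01, epochs = 500L, batch_size = 32L) {
  stopifnot(is_count(ann_hidden), is_count(lstm_hidden), is_count(epochs),
            is_count(batch_size), lr > 0)
  structure(list(ann_hidden = as.integer(ann_hidden),
                 lstm_hidden = as.integer(lstm_hidden),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "ann_lstm_config")
}

ann_lstm_init <- function(n_in, cfg, n_out = n_score_classes()) {
  h1 <- cfg$ann_hidden
  h2 <- cfg$lstm_hidden
  list(W1 = glorot(n_in, h1), b1 = numeric(h1),
       Wi = glorot(h1, h2), bi = numeric(h2),
       Wf = glorot(h1, h2), bf = numeric(h2),
       Wg = glorot(h1, h2), bg = numeric(h2),
       Wo = glorot(h1, h2), bo = numeric(h2),
       Wout = glorot(h2, n_out), bout = numeric(n_out))
}

# forward pass; the LSTM consumes the dense embedding as a length-1
# sequence from zero initial state, so the forget gate multiplies a zero
# cell state and only the input/candidate/output gates shape the output
ann_lstm_forward <- function(p, X) {
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  H1 <- relu(Z1)
  I <- sigmoid(sweep(H1 %*% p$Wi, 2, p$bi, "+"))
  G <- tanh(sweep(H1 %*% p$Wg, 2, p$bg, "+"))
  O <- sigmoid(sweep(H1 %*% p$Wo, 2, p$bo, "+"))
  C <- I * G
  Ct <- tanh(C)
  H <- O * Ct
  logits <- sweep(H %*% p$Wout, 2, p$bout, "+")
  list(logits = logits,
       cache = list(X = X, Z1 = Z1, H1 = H1, I = I, G = G, O = O,
                    C = C, Ct = Ct, H = H))
}

ann_lstm_backward <- function(p, cache, dlogits) {
  with(cache, {
    dWout <- crossprod(H, dlogits)
    dbout <- colSums(dlogits)
    dH <- tcrossprod(dlogits, p$Wout)
    dO <- dH * Ct
    dC <- dH * O * (1 - Ct^2)
    dI <- dC * G
    dG <- dC * I
    dzo <- dO * O * (1 - O)
    dzi <- dI * I * (1 - I)
    dzg <- dG * (1 - G^2)
    dH1 <- tcrossprod(dzi, p$Wi) + tcrossprod(dzg, p$Wg) +
      tcrossprod(dzo, p$Wo)
    dZ1 <- dH1 * (Z1 > 0)
    list(W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
         Wi = crossprod(H1, dzi), bi = colSums(dzi),
         Wf = p$Wf * 0, bf = p$bf * 0,
         Wg = crossprod(H1, dzg), bg = colSums(dzg),
         Wo = crossprod(H1, dzo), bo = colSums(dzo),
         Wout = dWout, bout = dbout)
  })
}

#' Fit the ANN-LSTM branch
#'
#' Inputs are standardised per feature (training-set mean and standard
#' deviation, stored in the model and reapplied at prediction). Raw
#' fluorescence features are all positive, which makes every input
#' coordinate push a dense ReLU unit's weights in the same direction; at
#' the reference learning rate this can kill the whole layer within a few
#' Adam steps, and centring removes that failure mode.
#'
#' @param X numeric `n x 192` feature matrix.
#' @param y integer class indices 0..10.
#' @param config an [ann_lstm_config()].
#' @param seed integer seed (initialisation and minibatch shuffles).
#' @param verbose print the loss every 50 epochs.
#' @return an object of class `ann_lstm` with `predict_proba()` /
#'   `predict()` methods and the per-epoch `loss_history`.
#' @export
fit_ann_lstm <- function(X, y, config = ann_lstm_config(), seed = 1L,
                         verbose = FALSE) {
  X <- check_deep_xy(X, y)
  y1 <- as.integer(y) + 1L
  feat_mean <- colMeans(X)
  feat_sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2, feat_mean), 2, feat_sd, "/")
  set.seed(seed)
  p <- ann_lstm_init(ncol(X), config)
  st <- adam_new(p)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    blocks <- batch_blocks(nrow(X), config$batch_size)
    ep_loss <- 0
    for (ib in blocks) {
      fw <- ann_lstm_forward(p, X[ib, , drop = FALSE])
      sx <- softmax_xent(fw$logits, y1[ib])
      if (!is.finite(sx$loss)) {
        stop_talsrx("ANN-LSTM: non-finite loss at epoch %d (lr = %g)",
                    ep, config$lr)
      }
      gr <- ann_lstm_backward(p, fw$cache, sx$dlogits)
      up <- adam_update(p, gr, st, config$lr)
      p <- up$params
      st <- up$state
      ep_loss <- ep_loss + sx$loss * length(ib)
    }
    losses[ep] <- ep_loss / nrow(X)
    if (verbose && ep %% 50 == 0) {
      message(sprintf("ann_lstm epoch %d: loss %.5f", ep, losses[ep]))
    }
  }
  structure(list(params = p, config = config, seed = seed,
                 n_features = ncol(X), loss_history = losses,
                 feat_mean = feat_mean, feat_sd = feat_sd),
            class = "ann_lstm")
}

#' @export
print.ann_lstm <- function(x, ...) {
  cat(sprintf("<ann_lstm> dense %d -> %d (ReLU) -> LSTM %d -> 11 classes\n",
              x$n_features, x$config$ann_hidden, x$config$lstm_hidden))
  cat(sprintf("  trained %d epochs, final loss %.5f\n",
              x$config$epochs, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
predict_proba.ann_lstm <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_talsrx("expected %d feature columns, got %d",
                object$n_features, ncol(X))
  }
  X <- sweep(sweep(X, 2, object$feat_mean), 2, object$feat_sd, "/")
  P <- softmax_rows(ann_lstm_forward(object$params, X)$logits)
  colnames(P) <- as.character(0:10)
  P
}

#' @export
predict.ann_lstm <- function(object, newdata,
                             type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kasp_dataset")) newdata <- feature_matrix(newdata)
  P <- predict_proba(object, newdata)
  switch(type, prob = P,
         class = as.integer(max.col(P, ties.method = "first") - 1L),
         score = decode_label(max.col(P, ties.method = "first") - 1L))
}
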