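#' Configuration of the Transformer branch
#'
#' Each plate is tokenised as 96 wells with 2 channels (HEX, FAM). Tokens
#' are linearly embedded to `d_model`, passed through `n_layers` encoder
#' layers (multi-head self-attention, residual + layer norm, position-wise
#' feed-forward, residual + layer norm, dropout on both sub-layer outputs),
#' mean-pooled over tokens, and mapped to the eleven class logits. Wells
#' form an unordered set, so no positional encoding is added by default
#' (switchable). Defaults are the reference configuration (`nhead = 6`,
#' `dropout = 0.01`, `lr = 0.001`, `epochs = 500`) with `d_model = 48`,
#' divisible by the six heads.
#'
#' @param d_model embedding width; must be divisible by `nhead`.
#' @param nhead number of attention heads.
#' @param n_layers number of encoder layers.
#' @param dim_ff feed-forward inner width.
#' @param dropout dropout probability (training only).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param n_tokens,in_dim token count and channels per token.
#' @param positional add sinusoidal positional encodings.
#' @return a `transformer_config` list.
#' @export
transformer_config <- function(d_model = 48L, nhead = 6L, n_layers = 3L,
                               dim_ff = 96L, dropout = 0.01, lr = 0.001,
                               epochs = 500L, batch_size = 32L,
                               n_tokens = 96L, in_dim = 2L,
                               positional = FALSE) {
  stopifnot(is_count(d_model), is_count(nhead), is_count(n_layers),
            is_count(dim_ff), is_count(epochs), is_count(batch_size),
            is_count(n_tokens), is_count(in_dim),
            dropout >= 0, dropout < 1, lr > 0)
  if (d_model %% nhead != 0) {
    stop_talsrx("d_model (%d) must be divisible by nhead (%d)", d_model, nhead)
  }
  structure(list(d_model = as.integer(d_model), nhead = as.integer(nhead),
                 n_layers = as.integer(n_layers), dim_ff = as.integer(dim_ff),
                 dropout = dropout, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_tokens = as.integer(n_tokens), in_dim = as.integer(in_dim),
                 positional = positional),
            class = "transformer_config")
}

transformer_init <- function(cfg, n_out = n_score_classes()) {
  d <- cfg$d_model
  p <- list(Wemb = glorot(cfg$in_dim, d), bemb = numeric(d))
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(s) paste0("L", l, "_", s)
    p[[nm("Wq")]] <- glorot(d, d); p[[nm("bq")]] <- numeric(d)
    p[[nm("Wk")]] <- glorot(d, d); p[[nm("bk")]] <- numeric(d)
    p[[nm("Wv")]] <- glorot(d, d); p[[nm("bv")]] <- numeric(d)
    p[[nm("Wo")]] <- glorot(d, d); p[[nm("bo")]] <- numeric(d)
    p[[nm("g1")]] <- rep(1, d);    p[[nm("be1")]] <- numeric(d)
    p[[nm("Wf1")]] <- glorot(d, cfg$dim_ff); p[[nm("bf1")]] <- numeric(cfg$dim_ff)
    p[[nm("Wf2")]] <- glorot(cfg$dim_ff, d); p[[nm("bf2")]] <- numeric(d)
    p[[nm("g2")]] <- rep(1, d);    p[[nm("be2")]] <- numeric(d)
  }
  p$Wcls <- glorot(d, n_out)
  p$bcls <- numeric(n_out)
  p
}

# reshape a batch of interleaved feature rows into stacked token matrices:
# rows are sample-major blocks of n_tokens, columns the in_dim channels
tokenize_batch <- function(X, cfg) {
  arr <- array(t(X), dim = c(cfg$in_dim, cfg$n_tokens, nrow(X)))
  matrix(aperm(arr, c(2, 3, 1)), nrow(X) * cfg$n_tokens, cfg$in_dim)
}

sin_positional <- function(T_, d) {
  pos <- seq_len(T_) - 1
  i <- seq_len(d) - 1
  ang <- outer(pos, 1 / 10000^(2 * (i %/% 2) / d))
  PE <- matrix(0, T_, d)
  PE[, i %% 2 == 0] <- sin(ang[, i %% 2 == 0])
  PE[, i %% 2 == 1] <- cos(ang[, i %% 2 == 1])
  PE
}

layernorm_fwd <- function(Xm, g, b, eps = 1e-5) {
  n <- nrow(Xm); d <- ncol(Xm)
  mu <- .rowMeans(Xm, n, d)
  xc <- Xm - mu
  sig <- sqrt(.rowMeans(xc^2, n, d) + eps)
  xhat <- xc / sig
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat, sig = sig)
}

layernorm_bwd <- function(dy, cache, g) {
  n <- nrow(dy); d <- ncol(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- (dxhat - .rowMeans(dxhat, n, d) -
           cache$xhat * .rowMeans(dxhat * cache$xhat, n, d)) / cache$sig
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

drop_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * m, 1, 1 - p) / (1 - p), n, m)
}

transformer_forward <- function(p, X, cfg, training = FALSE, Xt = NULL) {
  T_ <- cfg$n_tokens
  d <- cfg$d_model
  H <- cfg$nhead
  dh <- d %/% H
  if (is.null(Xt)) Xt <- tokenize_batch(X, cfg)
  B <- nrow(Xt) %/% T_
  E <- sweep(Xt %*% p$Wemb, 2, p$bemb, "+")
  if (isTRUE(cfg$positional)) {
    E <- E + sin_positional(T_, d)[rep(seq_len(T_), B), ]
  }
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(s) p[[paste0("L", l, "_", s)]]
    Qm <- sweep(E %*% nm("Wq"), 2, nm("bq"), "+")
    Km <- sweep(E %*% nm("Wk"), 2, nm("bk"), "+")
    Vm <- sweep(E %*% nm("Wv"), 2, nm("bv"), "+")
    O <- matrix(0, B * T_, d)
    A_all <- vector("list", B)
    # heads are processed jointly: queries are stacked head-block-wise and
    # zero-padded outside their head's columns, so one matrix product gives
    # all per-head score blocks and one softmax normalises them all
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T_ + seq_len(T_)
      Qxp <- matrix(0, H * T_, d)
      for (h in seq_len(H)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        Qxp[(h - 1L) * T_ + seq_len(T_), ch] <- Qm[rb, ch]
      }
      Sst <- tcrossprod(Qxp, Km[rb, , drop = FALSE]) / sqrt(dh)
      Ast <- softmax_rows(Sst)
      Ofull <- Ast %*% Vm[rb, , drop = FALSE]
      for (h in seq_len(H)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        O[rb, ch] <- Ofull[(h - 1L) * T_ + seq_len(T_), ch]
      }
      A_all[[b]] <- Ast
    }
    AttnOut <- sweep(O %*% nm("Wo"), 2, nm("bo"), "+")
    M1 <- if (training) drop_mask(B * T_, d, cfg$dropout) else NULL
    R1 <- E + if (is.null(M1)) AttnOut else AttnOut * M1
    ln1 <- layernorm_fwd(R1, nm("g1"), nm("be1"))
    N1 <- ln1$out
    Zf <- sweep(N1 %*% nm("Wf1"), 2, nm("bf1"), "+")
    Hf <- relu(Zf)
    F2 <- sweep(Hf %*% nm("Wf2"), 2, nm("bf2"), "+")
    M2 <- if (training) drop_mask(B * T_, d, cfg$dropout) else NULL
    R2 <- N1 + if (is.null(M2)) F2 else F2 * M2
    ln2 <- layernorm_fwd(R2, nm("g2"), nm("be2"))
    caches[[l]] <- list(E = E, Qm = Qm, Km = Km, Vm = Vm, A_all = A_all,
                        O = O, M1 = M1, ln1 = ln1, N1 = N1, Zf = Zf,
                        Hf = Hf, M2 = M2, ln2 = ln2)
    E <- ln2$out
  }
  grp <- rep(seq_len(B), each = T_)
  pooled <- rowsum(E, grp) / T_
  logits <- sweep(pooled %*% p$Wcls, 2, p$bcls, "+")
  list(logits = logits, E_final = E, pooled = pooled, caches = caches,
       Xt = Xt, B = B)
}

transformer_backward <- function(p, fw, cfg, dlogits) {
  B <- fw$B
  T_ <- cfg$n_tokens
  d <- cfg$d_model
  H <- cfg$nhead
  dh <- d %/% H
  g <- list()
  g$Wcls <- crossprod(fw$pooled, dlogits)
  g$bcls <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, p$Wcls)
  dE <- dpooled[rep(seq_len(B), each = T_), , drop = FALSE] / T_
  for (l in rev(seq_len(cfg$n_layers))) {
    ca <- fw$caches[[l]]
    nm <- function(s) p[[paste0("L", l, "_", s)]]
    gn <- function(s) paste0("L", l, "_", s)
    lb2 <- layernorm_bwd(dE, ca$ln2, nm("g2"))
    g[[gn("g2")]] <- lb2$dg
    g[[gn("be2")]] <- lb2$db
    dR2 <- lb2$dx
    dN1 <- dR2
    dF2 <- if (is.null(ca$M2)) dR2 else dR2 * ca$M2
    g[[gn("Wf2")]] <- crossprod(ca$Hf, dF2)
    g[[gn("bf2")]] <- colSums(dF2)
    dHf <- tcrossprod(dF2, nm("Wf2"))
    dZf <- dHf * (ca$Zf > 0)
    g[[gn("Wf1")]] <- crossprod(ca$N1, dZf)
    g[[gn("bf1")]] <- colSums(dZf)
    dN1 <- dN1 + tcrossprod(dZf, nm("Wf1"))
    lb1 <- layernorm_bwd(dN1, ca$ln1, nm("g1"))
    g[[gn("g1")]] <- lb1$dg
    g[[gn("be1")]] <- lb1$db
    dR1 <- lb1$dx
    dE_layer <- dR1
    dAttnOut <- if (is.null(ca$M1)) dR1 else dR1 * ca$M1
    g[[gn("Wo")]] <- crossprod(ca$O, dAttnOut)
    g[[gn("bo")]] <- colSums(dAttnOut)
    dO <- tcrossprod(dAttnOut, nm("Wo"))
    dQm <- matrix(0, B * T_, d)
    dKm <- matrix(0, B * T_, d)
    dVm <- matrix(0, B * T_, d)
    # mirror of the stacked-head forward: gradients w.r.t. the zero-padded
    # stacked queries keep head blocks separated, so one product per factor
    # recovers all heads' gradients at once
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T_ + seq_len(T_)
      Ast <- ca$A_all[[b]]
      dOxp <- matrix(0, H * T_, d)
      Qxp <- matrix(0, H * T_, d)
      for (h in seq_len(H)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        hr <- (h - 1L) * T_ + seq_len(T_)
        dOxp[hr, ch] <- dO[rb, ch]
        Qxp[hr, ch] <- ca$Qm[rb, ch]
      }
      dAst <- tcrossprod(dOxp, ca$Vm[rb, , drop = FALSE])
      dVm[rb, ] <- crossprod(Ast, dOxp)
      dSst <- Ast * (dAst - .rowSums(dAst * Ast, H * T_, T_))
      dKm[rb, ] <- crossprod(dSst, Qxp) / sqrt(dh)
      dQfull <- dSst %*% ca$Km[rb, , drop = FALSE] / sqrt(dh)
      for (h in seq_len(H)) {
        ch <- (h - 1L) * dh + seq_len(dh)
        dQm[rb, ch] <- dQfull[(h - 1L) * T_ + seq_len(T_), ch]
      }
    }
    g[[gn("Wq")]] <- crossprod(ca$E, dQm)
    g[[gn("bq")]] <- colSums(dQm)
    g[[gn("Wk")]] <- crossprod(ca$E, dKm)
    g[[gn("bk")]] <- colSums(dKm)
    g[[gn("Wv")]] <- crossprod(ca$E, dVm)
    g[[gn("bv")]] <- colSums(dVm)
    dE <- dE_layer + tcrossprod(dQm, nm("Wq")) +
      tcrossprod(dKm, nm("Wk")) + tcrossprod(dVm, nm("Wv"))
  }
  g$Wemb <- crossprod(fw$Xt, dE)
  g$bemb <- colSums(dE)
  g[names(p)]
}

#' Fit the Transformer branch
#'
#' @param X numeric `n x (n_tokens * in_dim)` feature matrix (interleaved
#'   channel layout, as produced by [build_feature_vector()]).
#' @param y integer class indices 0..10.
#' @param config a [transformer_config()].
#' @param seed integer seed.
#' @param verbose print the loss every 10 epochs.
#' @return an object of class `kasp_transformer` with `predict_proba()` /
#'   `predict()` methods and the per-epoch `loss_history`. Dropout is
#'   active only during training; inference is deterministic.
#' @export
fit_transformer <- function(X, y, config = transformer_config(), seed = 1L,
                            verbose = FALSE) {
  X <- check_deep_xy(X, y)
  if (ncol(X) != config$n_tokens * config$in_dim) {
    stop_talsrx("expected %d feature columns (%d tokens x %d channels), got %d",
                config$n_tokens * config$in_dim, config$n_tokens,
                config$in_dim, ncol(X))
  }
  y1 <- as.integer(y) + 1L
  set.seed(seed)
  p <- transformer_init(config)
  st <- adam_new(p)
  losses <- numeric(config$epochs)
  T_ <- config$n_tokens
  Xt_all <- tokenize_batch(X, config) # tokenize once, slice per batch
  for (ep in seq_len(config$epochs)) {
    blocks <- batch_blocks(nrow(X), config$batch_size)
    ep_loss <- 0
    for (ib in blocks) {
      rows <- rep((ib - 1L) * T_, each = T_) + seq_len(T_)
      fw <- transformer_forward(p, NULL, config, training = TRUE,
                                Xt = Xt_all[rows, , drop = FALSE])
      sx <- softmax_xent(fw$logits, y1[ib])
      if (!is.finite(sx$loss)) {
        stop_talsrx("transformer: non-finite loss at epoch %d (lr = %g)",
                    ep, config$lr)
      }
      gr <- transformer_backward(p, fw, config, sx$dlogits)
      up <- adam_update(p, gr, st, config$lr)
      p <- up$params
      st <- up$state
      ep_loss <- ep_loss + sx$loss * length(ib)
    }
    losses[ep] <- ep_loss / nrow(X)
    if (verbose && ep %% 10 == 0) {
      message(sprintf("transformer epoch %d: loss %.5f", ep, losses[ep]))
    }
  }
  structure(list(params = p, config = config, seed = seed,
                 n_features = ncol(X), loss_history = losses),
            class = "kasp_transformer")
}

#' @export
print.kasp_transformer <- function(x, ...) {
  cat(sprintf("<kasp_transformer> %d tokens x %d ch -> d_model %d, %d layers, %d heads\n",
              x$config$n_tokens, x$config$in_dim, x$config$d_model,
              x$config$n_layers, x$config$nhead))
  cat(sprintf("  trained %d epochs, final loss %.5f\n",
              x$config$epochs, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
predict_proba.kasp_transformer <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_talsrx("expected %d feature columns, got %d",
                object$n_features, ncol(X))
  }
  T_ <- object$config$n_tokens
  Xt_all <- tokenize_batch(X, object$config)
  chunks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / 128))
  P <- do.call(rbind, lapply(chunks, function(ix) {
    rows <- rep((ix - 1L) * T_, each = T_) + seq_len(T_)
    softmax_rows(transformer_forward(object$params, NULL, object$config,
                                     Xt = Xt_all[rows, , drop = FALSE])$logits)
  }))
  colnames(P) <- as.character(0:10)
  P
}

#' @export
predict.kasp_transformer <- function(object, newdata,
                                     type = c("prob", "class", "score"),
                                     ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kasp_dataset")) newdata <- feature_matrix(newdata)
  P <- predict_proba(object, newdata)
  switch(type, prob = P,
         class = as.integer(max.col(P, ties.method = "first") - 1L),
         score = decode_label(max.col(P, ties.method = "first") - 1L))
}
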