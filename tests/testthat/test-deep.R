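numeric_grad_check <- function(loss_fn, params, grads, per_param = 4,
                               eps = 1e-6) {
  base <- loss_fn(params)
  maxerr <- 0
  for (nm in names(params)) {
    k_set <- sample(seq_along(params[[nm]]),
                    min(per_param, length(params[[nm]])))
    for (k in k_set) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (loss_fn(p2) - base) / eps
      maxerr <- max(maxerr, abs(num - grads[[nm]][k]))
    }
  }
  maxerr
}

test_that("ANN-LSTM backpropagation matches numerical gradients", {
  set.seed(42)
  cfg <- ann_lstm_config(ann_hidden = 7, lstm_hidden = 5, epochs = 1)
  X <- matrix(rnorm(24), 4, 6)
  y1 <- c(1L, 3L, 5L, 11L)
  p <- talsrx:::ann_lstm_init(6, cfg)
  fw <- talsrx:::ann_lstm_forward(p, X)
  sx <- talsrx:::softmax_xent(fw$logits, y1)
  gr <- talsrx:::ann_lstm_backward(p, fw$cache, sx$dlogits)
  loss_fn <- function(p) {
    talsrx:::softmax_xent(talsrx:::ann_lstm_forward(p, X)$logits, y1)$loss
  }
  expect_lt(numeric_grad_check(loss_fn, p, gr), 1e-5)
})

test_that("Transformer backpropagation matches numerical gradients", {
  set.seed(7)
  cfg <- transformer_config(d_model = 8, nhead = 2, n_layers = 2,
                            dim_ff = 10, dropout = 0, epochs = 1,
                            n_tokens = 5, in_dim = 2)
  X <- matrix(rnorm(30), 3, 10)
  y1 <- c(2L, 7L, 9L)
  p <- talsrx:::transformer_init(cfg)
  fw <- talsrx:::transformer_forward(p, X, cfg)
  sx <- talsrx:::softmax_xent(fw$logits, y1)
  gr <- talsrx:::transformer_backward(p, fw, cfg, sx$dlogits)
  loss_fn <- function(p) {
    talsrx:::softmax_xent(talsrx:::transformer_forward(p, X, cfg)$logits,
                          y1)$loss
  }
  expect_lt(numeric_grad_check(loss_fn, p, gr), 1e-4)
})

test_that("the ANN-LSTM memorises a small two-class set", {
  blobs <- make_blobs(n_per = 10, p = 192, sep = 1.5, seed = 5,
                      classes = c(4L, 6L))
  m <- fit_ann_lstm(blobs$X, blobs$y, ann_lstm_config(epochs = 200), seed = 2)
  P <- predict_proba(m, blobs$X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_equal(mean(predict(m, blobs$X, type = "class") == blobs$y), 1)
  expect_true(all(is.finite(m$loss_history)))
  expect_lt(utils::tail(m$loss_history, 1), m$loss_history[1])
})

test_that("deep fits are reproducible under a fixed seed", {
  blobs <- make_blobs(n_per = 8, p = 192, sep = 2, seed = 6,
                      classes = c(0L, 10L))
  m1 <- fit_ann_lstm(blobs$X, blobs$y, ann_lstm_config(epochs = 20), seed = 3)
  m2 <- fit_ann_lstm(blobs$X, blobs$y, ann_lstm_config(epochs = 20), seed = 3)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(predict_proba(m1, blobs$X), predict_proba(m2, blobs$X))

  cfg <- transformer_config(epochs = 2)
  t1 <- fit_transformer(blobs$X, blobs$y, cfg, seed = 3)
  t2 <- fit_transformer(blobs$X, blobs$y, cfg, seed = 3)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_identical(predict_proba(t1, blobs$X), predict_proba(t2, blobs$X))
})

test_that("transformer configuration enforces head divisibility", {
  expect_s3_class(transformer_config(d_model = 48, nhead = 6),
                  "transformer_config")
  expect_error(transformer_config(d_model = 50, nhead = 6), "divisible")
})

test_that("transformer inference is deterministic (dropout is train-only)", {
  dat <- small_plate_data()
  m <- fit_transformer(dat$X[1:40, ], dat$y[1:40],
                       transformer_config(epochs = 2), seed = 1)
  P1 <- predict_proba(m, dat$X[41:50, ])
  P2 <- predict_proba(m, dat$X[41:50, ])
  expect_identical(P1, P2)
  expect_true(all(abs(rowSums(P1) - 1) < 1e-6))
})

test_that("the transformer separates the extreme rubric classes", {
  train <- generate_dataset(c("100" = 50, "0" = 50), seed = 31, jitter = 0)
  test <- kasp_dataset(c(
    lapply(1:15, function(s) sample_plate(zero_noise_spec(100), seed = 3000 + s)),
    lapply(1:15, function(s) sample_plate(default_spec(0), seed = 4000 + s))))
  m <- fit_transformer(feature_matrix(train),
                       encode_label(dataset_labels(train)),
                       transformer_config(epochs = 25), seed = 4)
  pred <- predict(m, test, type = "class")
  expect_identical(pred, encode_label(dataset_labels(test)))
  expect_lt(utils::tail(m$loss_history, 1), m$loss_history[1])
})
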