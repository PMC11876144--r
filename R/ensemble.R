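#' Soft-voting fusion of probability matrices
#'
#' Weighted average of row-stochastic class-probability matrices,
#' renormalised by the weight sum: `fused = sum_m w_m P_m / sum_m w_m`.
#' Rescaling all weights by a positive constant changes neither the fused
#' matrix nor any argmax decision.
#'
#' @param prob_matrices list of equal-shape row-stochastic matrices.
#' @param weights non-negative weights, one per matrix, not all zero.
#' @return the fused row-stochastic matrix.
#' @examples
#' p1 <- matrix(c(0.6, 0.4), 1); p2 <- matrix(c(0.2, 0.8), 1)
#' p3 <- matrix(c(0.5, 0.5), 1)
#' soft_vote(list(p1, p2, p3), c(0.95, 0.55, 0.25))
#' @export
soft_vote <- function(prob_matrices, weights) {
  if (!is.list(prob_matrices) || length(prob_matrices) == 0L) {
    stop_talsrx("prob_matrices must be a non-empty list")
  }
  if (length(weights) != length(prob_matrices)) {
    stop_talsrx("need one weight per probability matrix")
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop_talsrx("weights must be >= 0 and not all zero")
  }
  dims <- lapply(prob_matrices, dim)
  if (length(unique(dims)) != 1L) {
    stop_talsrx("probability matrices must share the same shape")
  }
  fused <- Reduce(`+`, Map(function(P, w) w * P, prob_matrices, weights))
  fused / sum(weights)
}

#' Grid search for soft-voting weights
#'
#' Exhaustive search over the weight lattice `{0, step, ..., 1}^m`
#' (excluding the all-zero point) maximising validation accuracy of the
#' fused argmax. By default ties keep the earliest lattice point in
#' lexicographic order. With `tol_samples > 0` the selection is
#' noise-aware: every lattice point within that many misclassified
#' validation samples of the maximum counts as statistically tied, and the
#' tie is resolved by validation macro one-vs-rest AUC (then lexicographic
#' order). On small validation splits this stops a one-sample accuracy
#' fluke from handing weight to a branch with badly ranked probabilities;
#' the package's own fitting paths use `tol_samples = 1`.
#'
#' @param prob_matrices list of validation probability matrices, one per
#'   model.
#' @param y_validation integer class indices 0..10.
#' @param grid_step lattice step; must divide 1 evenly (default 0.05).
#' @param tol_samples accuracy tolerance of the tie set, in validation
#'   samples (default 0: exact accuracy maximisation).
#' @return numeric weight vector on the lattice, named after the models
#'   when the list is named.
#' @export
grid_search_weights <- function(prob_matrices, y_validation,
                                grid_step = 0.05, tol_samples = 0) {
  if (length(y_validation) == 0L) stop_talsrx("empty validation set")
  steps <- 1 / grid_step
  if (abs(steps - round(steps)) > 1e-9) {
    stop_talsrx("grid_step must divide 1 evenly")
  }
  m <- length(prob_matrices)
  vals <- seq(0, 1, by = grid_step)
  grid <- as.matrix(expand.grid(rev(replicate(m, vals, simplify = FALSE)),
                                KEEP.OUT.ATTRS = FALSE))[, m:1, drop = FALSE]
  # expand.grid varies the first column fastest; after reversal the rows
  # run in lexicographic order of (w_1, ..., w_m)
  correct <- integer(nrow(grid))
  correct[1] <- -1L # all-zero point, excluded
  for (i in 2:nrow(grid)) {
    fused <- soft_vote(prob_matrices, grid[i, ])
    correct[i] <- sum(max.col(fused, ties.method = "first") - 1L ==
                        y_validation)
  }
  best <- max(correct)
  cand <- which(correct >= best - tol_samples & correct >= 0)
  pick <- cand[1]
  if (tol_samples > 0 && length(cand) > 1L &&
      length(unique(y_validation)) >= 2L) {
    aucs <- vapply(cand, function(i) {
      ovr_macro_auc(y_validation, soft_vote(prob_matrices, grid[i, ]))
    }, numeric(1))
    pick <- cand[which.max(aucs)] # which.max keeps the lex-first on ties
  }
  best_w <- grid[pick, ]
  names(best_w) <- names(prob_matrices)
  best_w
}

#' Configuration of the full fusion scorer
#'
#' @param val_frac fraction of the training set held out (stratified) for
#'   the voting-weight grid search.
#' @param grid_step weight lattice step.
#' @param tune tune the stacking learners ([tune_learner()]) or use the
#'   shipped tuned defaults.
#' @param budgets tuning budgets per learner.
#' @param stack_k stacking fold count.
#' @param ann an [ann_lstm_config()].
#' @param transformer a [transformer_config()].
#' @param weights optional fixed voting weights `(stacking, ann_lstm,
#'   transformer)`; skips the grid search. The shipped reference weights
#'   are `c(stacking = 0.95, ann_lstm = 0.55, transformer = 0.25)`.
#' @return a `tal_srx_config` list.
#' @export
tal_srx_config <- function(val_frac = 0.15, grid_step = 0.05, tune = FALSE,
                           budgets = list(svm = 8L, rf = 8L, xgb = 8L),
                           stack_k = 5L,
                           ann = ann_lstm_config(),
                           transformer = transformer_config(),
                           weights = NULL) {
  stopifnot(val_frac > 0, val_frac < 1)
  structure(list(val_frac = val_frac, grid_step = grid_step, tune = tune,
                 budgets = budgets, stack_k = stack_k, ann = ann,
                 transformer = transformer, weights = weights),
            class = "tal_srx_config")
}

# fit the three branches on (X, y); stack params may be pre-tuned
fit_branches <- function(X, y, config, seed, stack_params = NULL) {
  stack <- if (is.null(stack_params)) {
    fit_stack(X, y, tune = config$tune, budgets = config$budgets,
              k = config$stack_k, seed = derive_seed(seed, 21L))
  } else {
    fit_stack(X, y, tune = FALSE, params = stack_params,
              k = config$stack_k, seed = derive_seed(seed, 21L))
  }
  ann <- fit_ann_lstm(X, y, config$ann, seed = derive_seed(seed, 22L))
  trf <- fit_transformer(X, y, config$transformer,
                         seed = derive_seed(seed, 23L))
  list(stacking = stack, ann_lstm = ann, transformer = trf)
}

# stratified index split used for the internal weight-search holdout
holdout_indices <- function(y, val_frac, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, round_half_up(length(idx) * val_frac))
    val <- c(val, sample(idx, min(n_val, length(idx))))
  }
  sort(val)
}

#' Fit the TAL-SRX fusion scorer
#'
#' The full pipeline: an internal stratified validation split (default 15
#' percent) is carved from the training set; the stacking, ANN-LSTM and
#' Transformer branches are fitted on the remainder; soft-voting weights
#' are grid-searched on the validation split; finally all three branches
#' are refitted on the complete training set (reusing the tuned stacking
#' hyperparameters) and stored with the chosen weights.
#'
#' @param x training features: a numeric `n x 192` matrix or a labelled
#'   [kasp_dataset()].
#' @param y integer class indices 0..10 (ignored when `x` is a labelled
#'   dataset).
#' @param config a [tal_srx_config()].
#' @param seed integer root seed; every internal source of randomness is
#'   derived from it.
#' @return an object of class `tal_srx` with `predict()`, `print()`,
#'   `summary()` and `coef()` methods.
#' @seealso [predict_scores()], [soft_vote()], [grid_search_weights()]
#' @export
tal_srx <- function(x, y = NULL, config = tal_srx_config(), seed = 1L) {
  if (inherits(x, "kasp_dataset")) {
    y <- encode_label(dataset_labels(x))
    x <- feature_matrix(x)
  }
  X <- check_xy(x, y)
  if (is.null(config$weights)) {
    val <- holdout_indices(y, config$val_frac, derive_seed(seed, 11L))
    if (length(val) == 0L) stop_talsrx("empty validation split")
    fit_part <- fit_branches(X[-val, , drop = FALSE], y[-val], config,
                             seed = derive_seed(seed, 12L))
    val_probs <- lapply(fit_part, function(m) {
      predict_proba(m, X[val, , drop = FALSE])
    })
    weights <- grid_search_weights(val_probs, y[val], config$grid_step,
                                   tol_samples = 1)
    stack_params <- fit_part$stacking$params
  } else {
    weights <- config$weights
    stack_params <- NULL
    val <- integer(0)
  }
  branches <- fit_branches(X, y, config, seed = derive_seed(seed, 13L),
                           stack_params = stack_params)
  structure(list(branches = branches, weights = weights, config = config,
                 n_features = ncol(X), seed = seed,
                 n_train = nrow(X), n_validation = length(val)),
            class = "tal_srx")
}

#' @rdname tal_srx
#' @param train alias kept for pipeline-style calls.
#' @export
fit_tal_srx <- function(train, y = NULL, config = tal_srx_config(),
                        seed = 1L) {
  tal_srx(train, y, config = config, seed = seed)
}

#' @export
predict_proba.tal_srx <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_talsrx("expected %d feature columns, got %d",
                object$n_features, ncol(X))
  }
  probs <- lapply(object$branches, function(m) predict_proba(m, X))
  soft_vote(probs, object$weights)
}

#' Predict rubric scores from a fitted fusion model
#'
#' @param model a fitted [tal_srx()] model.
#' @param X feature matrix (192 columns) or [kasp_dataset()].
#' @return integer scores in `{0, 10, ..., 100}`.
#' @export
predict_scores <- function(model, X) {
  if (inherits(X, "kasp_dataset")) X <- feature_matrix(X)
  P <- predict_proba(model, X)
  decode_label(max.col(P, ties.method = "first") - 1L)
}

#' @export
predict.tal_srx <- function(object, newdata,
                            type = c("score", "class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kasp_dataset")) newdata <- feature_matrix(newdata)
  P <- predict_proba(object, newdata)
  switch(type, prob = P,
         class = as.integer(max.col(P, ties.method = "first") - 1L),
         score = decode_label(max.col(P, ties.method = "first") - 1L))
}

#' @export
coef.tal_srx <- function(object, ...) object$weights

#' @export
print.tal_srx <- function(x, ...) {
  cat("<tal_srx> multi-model fusion typing-effect scorer\n")
  cat(sprintf("  branches: stacking (PSO-SVM + RS-RF -> BO-XGBoost), ANN-LSTM, Transformer\n"))
  cat(sprintf("  voting weights: stacking %.2f, ann_lstm %.2f, transformer %.2f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  cat(sprintf("  trained on %d plates (%d held out for weight search)\n",
              x$n_train, x$n_validation))
  invisible(x)
}

#' @export
summary.tal_srx <- function(object, ...) {
  print(object)
  cat("\nStacking hyperparameters:\n")
  p <- object$branches$stacking$params
  cat("  svm:", paste(names(p$svm), vapply(p$svm, format, character(1)),
                      sep = "=", collapse = ", "), "\n")
  cat("  rf: ", paste(names(p$rf), vapply(p$rf, format, character(1)),
                      sep = "=", collapse = ", "), "\n")
  cat("  xgb:", paste(names(p$xgb), vapply(p$xgb, format, character(1)),
                      sep = "=", collapse = ", "), "\n")
  cat(sprintf("\nANN-LSTM final loss: %.5f | Transformer final loss: %.5f\n",
              utils::tail(object$branches$ann_lstm$loss_history, 1),
              utils::tail(object$branches$transformer$loss_history, 1)))
  invisible(object)
}
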