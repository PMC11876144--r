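#' Absolute-majority vote over per-tree outputs
#'
#' A class wins only if its votes exceed half of all votes cast; otherwise
#' the vote is rejected. This is the classical absolute-majority aggregation
#' rule for bagged tree ensembles. The stacking pipeline consumes vote
#' fractions as probabilities instead, but the rule is exposed on its own.
#'
#' @param votes either a vector of per-tree class votes or a one-hot
#'   `trees x classes` indicator matrix.
#' @return the winning class (same type as the votes), or `NA` when no class
#'   exceeds half of the votes (reject).
#' @examples
#' rf_majority_vote(c(4, 4, 4))        # unanimous -> 4
#' rf_majority_vote(c(1, 1, 2, 2))     # tie -> NA (reject)
#' @export
rf_majority_vote <- function(votes) {
  if (is.matrix(votes)) {
    if (nrow(votes) == 0L) stop_talsrx("empty vote set")
    counts <- colSums(votes)
    total <- sum(counts)
    labels <- colnames(votes) %||% seq_len(ncol(votes))
  } else {
    if (length(votes) == 0L) stop_talsrx("empty vote set")
    tab <- table(votes)
    counts <- as.numeric(tab)
    total <- sum(counts)
    labels <- names(tab)
    if (is.numeric(votes)) labels <- as.numeric(labels)
  }
  w <- which(counts > 0.5 * total)
  if (length(w) == 1L) labels[w] else NA
}

# --- parameter records ----------------------------------------------------

#' Default tuned hyperparameters of the three classical learners
#'
#' The shipped defaults are the tuned configurations of the reference
#' workflow: random forest `n_estimators = 202`, `max_depth = 34`,
#' `min_samples_split = 5`, `min_samples_leaf = 1`; RBF support vector
#' machine `C = 695.65`, `gamma = 0.0089`; XGBoost
#' `colsample_bytree = 0.87`, `learning_rate = 0.29`, `max_depth = 7`,
#' `n_estimators = 139`, `subsample = 0.83`.
#'
#' @param n_estimators,max_depth,min_samples_split,min_samples_leaf random
#'   forest controls.
#' @return a named parameter list.
#' @export
rf_params <- function(n_estimators = 202L, max_depth = 34L,
                      min_samples_split = 5L, min_samples_leaf = 1L) {
  stopifnot(is_count(n_estimators), is_count(max_depth),
            is_count(min_samples_split), is_count(min_samples_leaf),
            min_samples_leaf <= min_samples_split)
  list(n_estimators = as.integer(n_estimators),
       max_depth = as.integer(max_depth),
       min_samples_split = as.integer(min_samples_split),
       min_samples_leaf = as.integer(min_samples_leaf))
}

#' @rdname rf_params
#' @param C,gamma RBF support vector machine regularisation and kernel width.
#' @param kernel kernel family (only `"rbf"` is used here).
#' @export
svm_params <- function(C = 695.65, gamma = 0.0089, kernel = "rbf") {
  stopifnot(C > 0, gamma > 0)
  list(C = C, gamma = gamma, kernel = kernel)
}

#' @rdname rf_params
#' @param colsample_bytree,learning_rate,subsample XGBoost rate/fraction
#'   controls in (0, 1].
#' @export
xgb_params <- function(colsample_bytree = 0.87, learning_rate = 0.29,
                       max_depth = 7L, n_estimators = 139L, subsample = 0.83) {
  stopifnot(colsample_bytree > 0, colsample_bytree <= 1,
            learning_rate > 0, learning_rate <= 1,
            subsample > 0, subsample <= 1,
            is_count(max_depth), is_count(n_estimators))
  list(colsample_bytree = colsample_bytree, learning_rate = learning_rate,
       max_depth = as.integer(max_depth),
       n_estimators = as.integer(n_estimators), subsample = subsample)
}

# --- fitting --------------------------------------------------------------

new_learner <- function(kind, fit, classes, params, n_features) {
  structure(list(kind = kind, fit = fit, classes = classes,
                 params = params, n_features = n_features),
            class = "kasp_learner")
}

#' @export
print.kasp_learner <- function(x, ...) {
  cat(sprintf("<kasp_learner> %s over classes {%s}\n", x$kind,
              paste(x$classes, collapse = ",")))
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_talsrx("X rows must match length of y")
  if (any(!y %in% 0:10)) stop_talsrx("y must hold class indices 0..10")
  X
}

degenerate_learner <- function(kind, cls, params, n_features) {
  warning(sprintf("%s: single-class training data; degenerate classifier for class %d",
                  kind, cls))
  new_learner(paste0(kind, "_degenerate"), NULL, cls, params, n_features)
}

#' Fit the classical learners
#'
#' `fit_rf` fits a probability random forest (bootstrap resampling, random
#' feature subsets per split), `fit_svm` an RBF-kernel support vector
#' machine with one-vs-one multi-class decomposition and pairwise-coupled
#' sigmoid probability calibration, `fit_xgb` a gradient-boosted tree model
#' minimising multinomial loss plus complexity regularisation. All three
#' expose [predict_proba()] over the eleven score classes (classes absent
#' from training get probability zero) and are reproducible for a fixed
#' seed. Single-class training data yields a degenerate constant classifier
#' with a warning.
#'
#' @param X numeric feature matrix.
#' @param y integer class indices 0..10.
#' @param params from [rf_params()], [svm_params()] or [xgb_params()].
#' @param seed integer seed.
#' @return a `kasp_learner`.
#' @export
fit_rf <- function(X, y, params = rf_params(), seed = 1L) {
  X <- check_xy(X, y)
  cls <- sort(unique(y))
  if (length(cls) == 1L) return(degenerate_learner("rf", cls, params, ncol(X)))
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = cls),
    num.trees = params$n_estimators,
    max.depth = params$max_depth,
    min.node.size = params$min_samples_split,
    min.bucket = params$min_samples_leaf,
    probability = TRUE, num.threads = 1L, seed = seed)
  new_learner("rf", fit, cls, params, ncol(X))
}

#' @rdname fit_rf
#' @export
fit_svm <- function(X, y, params = svm_params(), seed = 1L) {
  X <- check_xy(X, y)
  cls <- sort(unique(y))
  if (length(cls) == 1L) return(degenerate_learner("svm", cls, params, ncol(X)))
  set.seed(seed) # probability calibration uses internal cross-validation
  fit <- e1071::svm(x = X, y = factor(y, levels = cls),
                    kernel = "radial", cost = params$C, gamma = params$gamma,
                    probability = TRUE, scale = FALSE)
  new_learner("svm", fit, cls, params, ncol(X))
}

#' @rdname fit_rf
#' @export
fit_xgb <- function(X, y, params = xgb_params(), seed = 1L) {
  X <- check_xy(X, y)
  cls <- sort(unique(y))
  if (length(cls) == 1L) return(degenerate_learner("xgb", cls, params, ncol(X)))
  ymap <- match(y, cls) - 1L
  fit <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "multi:softprob", num_class = length(cls),
      max_depth = params$max_depth, learning_rate = params$learning_rate,
      subsample = params$subsample,
      colsample_bytree = params$colsample_bytree,
      nthread = 1L, seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(X, label = ymap, nthread = 1L),
    nrounds = params$n_estimators, verbose = 0)
  new_learner("xgb", fit, cls, params, ncol(X))
}

#' Class-probability prediction over the eleven score classes
#'
#' @param object a fitted `kasp_learner` (or stack/ensemble model).
#' @param X numeric feature matrix with the training column count.
#' @param ... unused.
#' @return row-stochastic `n x 11` matrix, columns named `"0" ... "10"`.
#' @export
predict_proba <- function(object, X, ...) UseMethod("predict_proba")

full_proba <- function(P_obs, cls) {
  # embed probabilities over observed classes into the full 11-class simplex;
  # renormalise rows to absorb single-precision round-off from the backends
  out <- matrix(0, nrow(P_obs), n_score_classes(),
                dimnames = list(NULL, as.character(0:10)))
  out[, as.character(cls)] <- P_obs
  out / rowSums(out)
}

#' @export
predict_proba.kasp_learner <- function(object, X, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  if (ncol(X) != object$n_features) {
    stop_talsrx("expected %d feature columns, got %d",
                object$n_features, ncol(X))
  }
  if (grepl("_degenerate$", object$kind)) {
    return(full_proba(matrix(1, nrow(X), 1), object$classes))
  }
  P <- switch(object$kind,
    rf = stats::predict(object$fit, data = X, num.threads = 1L)$predictions,
    svm = {
      colnames(X) <- colnames(object$fit$SV) %||% colnames(X)
      pr <- attr(stats::predict(object$fit, X, probability = TRUE),
                 "probabilities")
      pr[, order(as.integer(colnames(pr))), drop = FALSE]
    },
    xgb = {
      p <- stats::predict(object$fit, X)
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(X), byrow = TRUE)
      p
    },
    stop_talsrx("unknown learner kind '%s'", object$kind))
  P <- as.matrix(P)
  full_proba(P, object$classes)
}

#' Hard class prediction
#'
#' Argmax of [predict_proba()], returned as class indices 0..10.
#' @inheritParams predict_proba
#' @export
predict_class <- function(object, X, ...) {
  P <- predict_proba(object, X, ...)
  as.integer(max.col(P, ties.method = "first") - 1L)
}

# --- tuning ---------------------------------------------------------------

#' Default search spaces for the three learners
#'
#' Spaces bracket the shipped tuned configurations so they are always
#' reachable: RF trees 50-400, depth 5-40; SVM `C` 1-1000 and `gamma`
#' 1e-4-1, both log-scaled; XGBoost depth 3-10, learning rate 0.01-0.3
#' (log), trees 50-300, subsampling fractions 0.5-1.
#'
#' @param kind `"rf"`, `"svm"` or `"xgb"`.
#' @return a [search_space()].
#' @export
default_space <- function(kind = c("rf", "svm", "xgb")) {
  kind <- match.arg(kind)
  switch(kind,
    rf = search_space(
      param_integer("n_estimators", 50, 400),
      param_integer("max_depth", 5, 40),
      param_integer("min_samples_split", 2, 10),
      param_integer("min_samples_leaf", 1, 5)),
    svm = search_space(
      param_real("C", 1, 1000, scale = "log"),
      param_real("gamma", 1e-4, 1, scale = "log")),
    xgb = search_space(
      param_integer("max_depth", 3, 10),
      param_real("learning_rate", 0.01, 0.3, scale = "log"),
      param_integer("n_estimators", 50, 300),
      param_real("subsample", 0.5, 1),
      param_real("colsample_bytree", 0.5, 1)))
}

# k near-equal random folds; stratified by y when requested
make_folds <- function(y, k = 5L, seed = 1L, stratify = FALSE) {
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

coerce_params <- function(kind, params) {
  switch(kind,
    rf = {
      p <- params
      p$min_samples_leaf <- min(p$min_samples_leaf %||% 1L,
                                p$min_samples_split %||% 2L)
      do.call(rf_params, p)
    },
    svm = do.call(svm_params, params),
    xgb = do.call(xgb_params, params))
}

fit_learner <- function(kind, X, y, params, seed) {
  switch(kind,
    rf = fit_rf(X, y, params, seed),
    svm = fit_svm(X, y, params, seed),
    xgb = fit_xgb(X, y, params, seed))
}

# mean k-fold cross-validated accuracy of one configuration; fits without
# probability machinery (hard predictions suffice for accuracy)
cv_accuracy <- function(kind, params, X, y, fold, seed) {
  k <- max(fold)
  acc <- numeric(k)
  for (j in seq_len(k)) {
    tr <- fold != j
    yhat <- cv_predict_class(kind, params, X[tr, , drop = FALSE], y[tr],
                             X[!tr, , drop = FALSE], derive_seed(seed, j))
    acc[j] <- mean(yhat == y[!tr])
  }
  mean(acc)
}

cv_predict_class <- function(kind, params, Xtr, ytr, Xte, seed) {
  cls <- sort(unique(ytr))
  if (length(cls) == 1L) return(rep(cls, nrow(Xte)))
  if (kind == "rf") {
    fit <- ranger::ranger(x = Xtr, y = factor(ytr, levels = cls),
                          num.trees = params$n_estimators,
                          max.depth = params$max_depth,
                          min.node.size = params$min_samples_split,
                          min.bucket = params$min_samples_leaf,
                          num.threads = 1L, seed = seed)
    as.integer(as.character(stats::predict(fit, data = Xte,
                                           num.threads = 1L)$predictions))
  } else if (kind == "svm") {
    set.seed(seed)
    fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = cls),
                      kernel = "radial", cost = params$C,
                      gamma = params$gamma, scale = FALSE)
    as.integer(as.character(stats::predict(fit, Xte)))
  } else {
    lrn <- fit_xgb(Xtr, ytr, params, seed)
    predict_class(lrn, Xte)
  }
}

#' Tune a learner by cross-validated accuracy
#'
#' Pairs each learner with its optimizer — random search for the random
#' forest, particle swarm for the SVM, Bayesian optimisation for XGBoost —
#' and maximises mean 5-fold cross-validated accuracy on the training data.
#' The pairing can be overridden.
#'
#' @param kind `"rf"`, `"svm"` or `"xgb"`.
#' @param X,y training features and class indices.
#' @param optimizer `"auto"` (the default pairing) or one of `"random"`,
#'   `"pso"`, `"bayes"`.
#' @param budget total number of objective evaluations (>= 1).
#' @param seed integer seed.
#' @param space optional [search_space()] override.
#' @param k number of cross-validation folds.
#' @return list with `params` (coerced parameter record), `cv_score` and the
#'   full `opt_result`.
#' @export
tune_learner <- function(kind = c("rf", "svm", "xgb"), X, y,
                         optimizer = "auto", budget = 20L, seed = 1L,
                         space = NULL, k = 5L) {
  kind <- match.arg(kind)
  if (!is_count(budget)) stop_talsrx("budget must be a positive integer")
  optimizer <- match.arg(optimizer, c("auto", "random", "pso", "bayes"))
  if (optimizer == "auto") {
    optimizer <- switch(kind, rf = "random", svm = "pso", xgb = "bayes")
  }
  space <- space %||% default_space(kind)
  X <- check_xy(X, y)
  fold <- make_folds(y, k = k, seed = derive_seed(seed, 91L), stratify = TRUE)
  objective <- function(params) {
    cv_accuracy(kind, coerce_params(kind, params), X, y, fold,
                derive_seed(seed, 17L))
  }
  res <- if (optimizer == "random" || budget < 3L) {
    random_search(objective, space, n_iter = budget, seed = seed)
  } else if (optimizer == "pso") {
    np <- max(2L, min(5L, budget %/% 2L))
    ni <- max(1L, ceiling(budget / np) - 1L)
    pso_optimize(objective, space, n_particles = np, n_iter = ni, seed = seed)
  } else {
    ninit <- max(2L, ceiling(budget / 3))
    bayes_optimize(objective, space, n_init = ninit,
                   n_iter = budget - ninit, seed = seed)
  }
  list(params = coerce_params(kind, res$best_params),
       cv_score = res$best_objective, optimizer = optimizer,
       opt_result = res)
}
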