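#' Out-of-fold meta-features from the two base learners
#'
#' The training set is randomly divided into `k` near-equal disjoint folds.
#' For each fold, each base learner is trained on the other `k - 1` folds
#' and predicts class probabilities on the held-out fold, so every
#' meta-feature row is produced by models that never saw that sample. The
#' rows concatenate the SVM probabilities and the RF probabilities
#' (`2 x 11 = 22` columns); classes absent from a training fold contribute
#' zero probability.
#'
#' @param X numeric `n x p` feature matrix.
#' @param y integer class indices 0..10.
#' @param k number of folds (>= 2, default 5).
#' @param seed integer seed (controls the fold draw and the fits).
#' @param base_fitters named list of two fitting functions
#'   `function(X, y, seed)` returning objects with a [predict_proba()]
#'   method; defaults to the tuned SVM and RF.
#' @param svm_params,rf_params parameter records for the default fitters.
#' @param fold optional pre-computed fold assignment (integer vector in
#'   `1..k`); drawn from `seed` when omitted.
#' @return list with `Z` (the `n x 22` meta-feature matrix) and
#'   `fold_assignments` (integer fold index per sample).
#' @export
oof_meta_features <- function(X, y, k = 5L, seed = 1L,
                              base_fitters = NULL,
                              svm_params = talsrx::svm_params(),
                              rf_params = talsrx::rf_params(),
                              fold = NULL) {
  X <- check_xy(X, y)
  if (!is_count(k) || k < 2) stop_talsrx("k must be an integer >= 2")
  if (is.null(base_fitters)) {
    base_fitters <- list(
      svm = function(X, y, seed) fit_svm(X, y, svm_params, seed),
      rf = function(X, y, seed) fit_rf(X, y, rf_params, seed))
  }
  if (is.null(fold)) fold <- make_folds(y, k = k, seed = seed, stratify = FALSE)
  n <- nrow(X)
  m <- length(base_fitters)
  Z <- matrix(NA_real_, n, m * n_score_classes())
  colnames(Z) <- as.vector(vapply(names(base_fitters), function(nm) {
    paste0(nm, "_p", 0:10)
  }, character(n_score_classes())))
  for (j in seq_len(k)) {
    tr <- fold != j
    for (b in seq_len(m)) {
      fit <- base_fitters[[b]](X[tr, , drop = FALSE], y[tr],
                               derive_seed(seed, j * 10L + b))
      cols <- (b - 1L) * n_score_classes() + seq_len(n_score_classes())
      Z[!tr, cols] <- predict_proba(fit, X[!tr, , drop = FALSE])
    }
  }
  list(Z = Z, fold_assignments = fold)
}

#' Fit the stacked-generalization model
#'
#' Two tuned base learners — a particle-swarm-tuned RBF SVM and a
#' random-search-tuned random forest — generate 5-fold out-of-fold class
#' probabilities, which a Bayesian-optimisation-tuned XGBoost meta-learner
#' combines with the original labels. After meta-training both base
#' learners are refit on the full training set for inference. Tuning runs
#' once on the full training set before out-of-fold construction.
#'
#' @param X numeric `n x p` training features.
#' @param y integer class indices 0..10 (at least two classes).
#' @param tune tune the three learners (`TRUE`) or use the supplied/default
#'   parameter records as-is.
#' @param budgets named list of tuning budgets (`svm`, `rf`, `xgb`).
#' @param params named list of parameter records (`svm`, `rf`, `xgb`) used
#'   when `tune = FALSE` (and as documentation of the tuned result
#'   otherwise).
#' @param k number of stacking folds.
#' @param seed integer root seed.
#' @return an object of class `kasp_stack`.
#' @seealso [predict_proba()], [tune_learner()]
#' @export
fit_stack <- function(X, y, tune = FALSE,
                      budgets = list(svm = 12L, rf = 12L, xgb = 12L),
                      params = list(svm = svm_params(), rf = rf_params(),
                                    xgb = xgb_params()),
                      k = 5L, seed = 1L) {
  X <- check_xy(X, y)
  if (length(unique(y)) < 2L) stop_talsrx("training data needs >= 2 classes")
  cv_scores <- NULL
  if (tune) {
    ts <- tune_learner("svm", X, y, budget = budgets$svm,
                       seed = derive_seed(seed, 1L))
    tr <- tune_learner("rf", X, y, budget = budgets$rf,
                       seed = derive_seed(seed, 2L))
    params$svm <- ts$params
    params$rf <- tr$params
    cv_scores <- c(svm = ts$cv_score, rf = tr$cv_score)
  }
  oof <- oof_meta_features(X, y, k = k, seed = derive_seed(seed, 3L),
                           svm_params = params$svm, rf_params = params$rf)
  if (tune) {
    tx <- tune_learner("xgb", oof$Z, y, budget = budgets$xgb,
                       seed = derive_seed(seed, 4L))
    params$xgb <- tx$params
    cv_scores <- c(cv_scores, xgb = tx$cv_score)
  }
  meta <- fit_xgb(oof$Z, y, params$xgb, seed = derive_seed(seed, 5L))
  base_svm <- fit_svm(X, y, params$svm, seed = derive_seed(seed, 6L))
  base_rf <- fit_rf(X, y, params$rf, seed = derive_seed(seed, 7L))
  structure(list(base_models = list(svm = base_svm, rf = base_rf),
                 meta_model = meta,
                 fold_assignments = oof$fold_assignments,
                 params = params, cv_scores = cv_scores,
                 n_features = ncol(X), seed = seed),
            class = "kasp_stack")
}

#' @export
print.kasp_stack <- function(x, ...) {
  cat("<kasp_stack> PSO-SVM + RS-RF base learners, BO-XGBoost meta-learner\n")
  cat(sprintf("  %d training samples in %d folds, %d features\n",
              length(x$fold_assignments), max(x$fold_assignments),
              x$n_features))
  invisible(x)
}

stack_meta_features <- function(model, X) {
  cbind(predict_proba(model$base_models$svm, X),
        predict_proba(model$base_models$rf, X))
}

#' @export
predict_proba.kasp_stack <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_talsrx("expected %d feature columns, got %d",
                object$n_features, ncol(X))
  }
  predict_proba(object$meta_model, stack_meta_features(object, X))
}

#' Predict class probabilities or scores from a stacked model
#'
#' @param object a `kasp_stack` from [fit_stack()].
#' @param newdata feature matrix (or [kasp_dataset()]).
#' @param type `"prob"` for the 11-class probability matrix, `"class"` for
#'   class indices, `"score"` for rubric scores.
#' @param ... unused.
#' @export
predict.kasp_stack <- function(object, newdata,
                               type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "kasp_dataset")) newdata <- feature_matrix(newdata)
  P <- predict_proba(object, newdata)
  switch(type,
    prob = P,
    class = as.integer(max.col(P, ties.method = "first") - 1L),
    score = decode_label(max.col(P, ties.method = "first") - 1L))
}
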