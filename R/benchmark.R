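#' Configuration of the end-to-end synthetic benchmark
#'
#' The default benchmark simulates 100 training and 30 test plates for each
#' of the eleven score classes (1430 plates), trains every individual model
#' and every fusion combination, and evaluates all of them on the common
#' test split. Deep-branch epochs and tuning budgets default to reduced
#' values sized for a single-CPU run; the branch defaults themselves
#' ([ann_lstm_config()], [transformer_config()]) keep the full reference
#' settings.
#'
#' @param n_train_per_class,n_test_per_class simulated plates per class.
#' @param jitter simulator spec jitter.
#' @param tune tune the stacking learners (small budgets) or use shipped
#'   defaults.
#' @param budgets tuning budgets per learner.
#' @param ann,transformer branch configurations.
#' @param val_frac,grid_step weight-search settings.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(n_train_per_class = 100L,
                             n_test_per_class = 30L,
                             jitter = 0.2,
                             tune = TRUE,
                             budgets = list(svm = 6L, rf = 8L, xgb = 5L),
                             ann = ann_lstm_config(epochs = 60L),
                             transformer = transformer_config(epochs = 14L),
                             val_frac = 0.15, grid_step = 0.05) {
  structure(list(n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 jitter = jitter, tune = tune, budgets = budgets,
                 ann = ann, transformer = transformer,
                 val_frac = val_frac, grid_step = grid_step),
            class = "benchmark_config")
}

metrics_row <- function(y_true, P) {
  rep <- eval_report(y_true, P)
  c(accuracy = rep$accuracy,
    precision = unname(rep$macro["precision"]),
    recall = unname(rep$macro["recall"]),
    f1 = unname(rep$macro["f1"]),
    kappa = rep$kappa,
    auc = rep$macro_auc)
}

#' Run the end-to-end synthetic benchmark
#'
#' Simulates a labelled plate population, trains ten models — the three
#' tuned single learners (RS-RF, PSO-SVM, BO-XGBoost), the two neural
#' branches, the stacked model, and four soft-voting combinations
#' (deep-only, stacking plus one deep branch each, and the full three-way
#' fusion) — and evaluates all of them on a common held-out test split.
#' All models train on the identical sub-train pool (the training
#' population minus the internal validation split used only for the
#' voting-weight grid searches), so the fusion rows combine exactly the
#' single-model rows' fits and the comparison is all-else-equal.
#' Deterministic for a fixed seed.
#'
#' @param config a [benchmark_config()].
#' @param seed integer root seed.
#' @param verbose print progress messages.
#' @return an object of class `kasp_benchmark`: `report` (one row per
#'   model with accuracy, macro precision/recall/F1, kappa, macro AUC),
#'   `weights` (grid-searched weights per combination), `probs` (test-set
#'   probability matrices), `y_test`, and the evaluated `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 1L,
                          verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  counts_tr <- stats::setNames(rep(config$n_train_per_class, 11),
                               seq(0, 100, by = 10))
  counts_te <- stats::setNames(rep(config$n_test_per_class, 11),
                               seq(0, 100, by = 10))
  say("simulating %d train / %d test plates",
      sum(counts_tr), sum(counts_te))
  train <- generate_dataset(counts_tr, seed = derive_seed(seed, 1L),
                            jitter = config$jitter)
  test <- generate_dataset(counts_te, seed = derive_seed(seed, 2L),
                           jitter = config$jitter)
  X <- feature_matrix(train)
  y <- encode_label(dataset_labels(train))
  Xte <- feature_matrix(test)
  yte <- encode_label(dataset_labels(test))

  # every compared model trains on the identical sub-train pool so that
  # the fusion rows combine exactly the single-model rows' fits and the
  # comparison is all-else-equal; the weight-search validation split is
  # seen by no model
  tcfg <- tal_srx_config(val_frac = config$val_frac,
                         grid_step = config$grid_step,
                         tune = config$tune, budgets = config$budgets,
                         ann = config$ann, transformer = config$transformer)
  val <- holdout_indices(y, config$val_frac, derive_seed(seed, 11L))
  Xtr <- X[-val, , drop = FALSE]
  ytr <- y[-val]
  say("fitting branches on %d plates (%d held out for weight search)",
      length(ytr), length(val))
  sub <- fit_branches(Xtr, ytr, tcfg, seed = derive_seed(seed, 12L))
  val_probs <- lapply(sub, function(m) {
    predict_proba(m, X[val, , drop = FALSE])
  })
  yval <- y[val]
  say("grid-searching voting weights")
  weights <- list(
    deep_vote = grid_search_weights(val_probs[c("ann_lstm", "transformer")],
                                    yval, config$grid_step, tol_samples = 1),
    stack_ann = grid_search_weights(val_probs[c("stacking", "ann_lstm")],
                                    yval, config$grid_step, tol_samples = 1),
    stack_transformer = grid_search_weights(
      val_probs[c("stacking", "transformer")], yval, config$grid_step,
      tol_samples = 1),
    tal_srx = grid_search_weights(val_probs, yval, config$grid_step,
                                  tol_samples = 1))

  say("tuning the standalone XGBoost")
  xgb_single <- if (config$tune) {
    tuned <- tune_learner("xgb", Xtr, ytr, budget = config$budgets$xgb,
                          seed = derive_seed(seed, 14L))
    fit_xgb(Xtr, ytr, tuned$params, seed = derive_seed(seed, 15L))
  } else {
    fit_xgb(Xtr, ytr, seed = derive_seed(seed, 15L))
  }

  say("evaluating on the test split")
  probs <- list(
    `RS-RF` = predict_proba(sub$stacking$base_models$rf, Xte),
    `PSO-SVM` = predict_proba(sub$stacking$base_models$svm, Xte),
    `BO-XGBoost` = predict_proba(xgb_single, Xte),
    `ANN-LSTM` = predict_proba(sub$ann_lstm, Xte),
    `Transformer` = predict_proba(sub$transformer, Xte))
  probs$Stacking <- predict_proba(sub$stacking, Xte)
  probs$`Deep vote` <- soft_vote(
    list(probs$`ANN-LSTM`, probs$Transformer), weights$deep_vote)
  probs$`Stacking+ANN-LSTM` <- soft_vote(
    list(probs$Stacking, probs$`ANN-LSTM`), weights$stack_ann)
  probs$`Stacking+Transformer` <- soft_vote(
    list(probs$Stacking, probs$Transformer), weights$stack_transformer)
  probs$`TAL-SRX` <- soft_vote(
    list(probs$Stacking, probs$`ANN-LSTM`, probs$Transformer),
    weights$tal_srx)

  report <- as.data.frame(t(vapply(probs, function(P) metrics_row(yte, P),
                                   numeric(6))))
  report <- cbind(model = rownames(report), report)
  rownames(report) <- NULL
  structure(list(report = report, weights = weights, probs = probs,
                 y_test = yte, config = config, seed = seed),
            class = "kasp_benchmark")
}

#' @export
print.kasp_benchmark <- function(x, ...) {
  cat(sprintf("<kasp_benchmark> seed %d, %d test plates\n",
              x$seed, length(x$y_test)))
  df <- x$report
  df[-1] <- lapply(df[-1], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  invisible(x)
}
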