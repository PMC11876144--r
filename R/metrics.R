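#' Confusion matrix over the eleven score classes
#'
#' @param y_true,y_pred integer class indices 0..10, equal length.
#' @return an 11 x 11 integer matrix, rows = true class, columns = predicted
#'   class, dimnames `"0" ... "10"`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_talsrx("y_true and y_pred must have equal length")
  }
  if (any(!y_true %in% 0:10) || any(!y_pred %in% 0:10)) {
    stop_talsrx("class indices must lie in 0..10")
  }
  cm <- table(factor(y_true, levels = 0:10), factor(y_pred, levels = 0:10))
  m <- matrix(as.integer(cm), n_score_classes(), n_score_classes(),
              dimnames = list(true = as.character(0:10),
                              pred = as.character(0:10)))
  m
}

#' Per-class and macro precision, recall, F1 and Jaccard ratio
#'
#' Per class: precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1 their
#' harmonic mean, and the Jaccard-style ratio `TP / (TP + FP + FN)` (which
#' in some write-ups is printed under the name "accuracy"; it is a distinct
#' per-class quantity and reported here separately — see
#' [overall_accuracy()] for the headline metric). Macro values are the
#' unweighted means over classes present in the truth; a class with a zero
#' denominator contributes 0.
#'
#' @param cm a [confusion()] matrix.
#' @return list with `per_class` (data frame) and `macro` (named vector of
#'   `precision`, `recall`, `f1`, `jaccard`).
#' @export
prf_macro <- function(cm) {
  if (!is.matrix(cm) || sum(cm) == 0) stop_talsrx("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  jaccard <- safe_div(tp, tp + fp + fn)
  present <- rowSums(cm) > 0
  per_class <- data.frame(class = rownames(cm) %||%
                            as.character(seq_len(nrow(cm)) - 1L),
                          precision = precision, recall = recall,
                          f1 = f1, jaccard = jaccard,
                          present = present, row.names = NULL)
  macro <- c(precision = mean(precision[present]),
             recall = mean(recall[present]),
             f1 = mean(f1[present]),
             jaccard = mean(jaccard[present]))
  list(per_class = per_class, macro = macro)
}

#' Overall accuracy
#'
#' Fraction of correct predictions, `trace(cm) / total`.
#'
#' @inheritParams confusion
#' @return a proportion in `[0, 1]`.
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_talsrx("no samples")
  if (length(y_true) != length(y_pred)) {
    stop_talsrx("y_true and y_pred must have equal length")
  }
  mean(y_true == y_pred)
}

#' Cohen's kappa and its agreement band
#'
#' Chance-corrected agreement `k = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace / total` and chance agreement
#' `p_e = sum_c row_c * col_c / total^2`. `kappa_band()` maps a kappa value
#' to the conventional six-level verbal scale (0.81-1.00 almost perfect,
#' 0.61-0.80 significant, 0.41-0.60 moderate, 0.21-0.40 fair, 0.00-0.20
#' very low, below 0 none/very poor).
#'
#' @param cm a confusion matrix (any square size).
#' @return `cohen_kappa`: a value in `[-1, 1]`, or `NA` with a warning when
#'   `p_e = 1` (all mass in one row and column).
#' @export
cohen_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_talsrx("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    warning("kappa undefined: chance agreement p_e = 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' @rdname cohen_kappa
#' @param kappa a kappa value.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa >= 0.81) "almost perfect agreement"
  else if (kappa >= 0.61) "significant agreement"
  else if (kappa >= 0.41) "moderate agreement"
  else if (kappa >= 0.21) "fair agreement"
  else if (kappa >= 0) "very low agreement"
  else "no or very poor agreement"
}

#' One-vs-rest kappa per class
#'
#' For each class, collapses the labels to binary (class vs rest) and
#' applies Cohen's kappa. Classes absent from both truth and prediction are
#' reported as `NA`.
#'
#' @inheritParams confusion
#' @return named numeric vector of length 11.
#' @export
per_class_kappa <- function(y_true, y_pred) {
  vapply(0:10, function(cl) {
    if (!cl %in% y_true && !cl %in% y_pred) return(NA_real_)
    bt <- as.integer(y_true == cl)
    bp <- as.integer(y_pred == cl)
    cm2 <- table(factor(bt, levels = 0:1), factor(bp, levels = 0:1))
    suppressWarnings(cohen_kappa(cm2))
  }, numeric(1)) |> stats::setNames(as.character(0:10))
}

# one-vs-rest AUC by the rank statistic (Mann-Whitney, ties counted half)
auc_rank <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores)
  n2 <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Macro one-vs-rest AUC
#'
#' For each class present in the truth, the AUC of that class's predicted
#' probability against all other samples (rank statistic; ties count one
#' half), macro-averaged over those classes.
#'
#' @param y_true integer class indices 0..10.
#' @param prob_matrix row-stochastic `n x 11` probability matrix.
#' @return the macro mean AUC.
#' @export
ovr_macro_auc <- function(y_true, prob_matrix) {
  prob_matrix <- as.matrix(prob_matrix)
  if (nrow(prob_matrix) != length(y_true)) {
    stop_talsrx("probability matrix rows must match length of y_true")
  }
  present <- sort(unique(y_true))
  if (length(present) < 2L) {
    stop_talsrx("one-vs-rest AUC undefined with a single class present")
  }
  aucs <- vapply(present, function(cl) {
    s <- prob_matrix[, cl + 1L]
    auc_rank(s[y_true == cl], s[y_true != cl])
  }, numeric(1))
  mean(aucs)
}

#' Per-sample score errors and score-band histograms
#'
#' `error_vector` is the elementwise absolute difference between true and
#' predicted rubric scores; `band_histogram` counts samples per score band.
#'
#' @param y_true_scores,y_pred_scores rubric scores in `{0, 10, ..., 100}`.
#' @param scores rubric scores.
#' @return `error_vector`: integer vector of absolute score differences;
#'   `band_histogram`: named integer vector of counts per band.
#' @export
error_vector <- function(y_true_scores, y_pred_scores) {
  check_score(y_true_scores)
  check_score(y_pred_scores)
  if (length(y_true_scores) != length(y_pred_scores)) {
    stop_talsrx("score vectors must have equal length")
  }
  abs(as.integer(y_true_scores) - as.integer(y_pred_scores))
}

#' @rdname error_vector
#' @export
band_histogram <- function(scores) {
  check_score(scores)
  tab <- table(factor(scores, levels = seq(0, 100, by = 10)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Full evaluation report
#'
#' Bundles the whole evaluation suite for one model on one test set:
#' confusion matrix, overall accuracy, per-class and macro
#' precision/recall/F1/Jaccard, overall and per-class one-vs-rest kappa with
#' the verbal agreement band, macro one-vs-rest AUC, the per-sample score
#' error vector, and true/predicted score-band histograms.
#'
#' @param y_true integer class indices 0..10.
#' @param prob_matrix row-stochastic `n x 11` probability matrix.
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(y_true, prob_matrix) {
  prob_matrix <- as.matrix(prob_matrix)
  y_pred <- as.integer(max.col(prob_matrix, ties.method = "first") - 1L)
  cm <- confusion(y_true, y_pred)
  prf <- prf_macro(cm)
  kap <- cohen_kappa(cm)
  auc <- if (length(unique(y_true)) >= 2L) {
    ovr_macro_auc(y_true, prob_matrix)
  } else NA_real_
  structure(
    list(confusion = cm,
         accuracy = overall_accuracy(y_true, y_pred),
         per_class = prf$per_class,
         macro = prf$macro,
         kappa = kap,
         kappa_band = kappa_band(kap),
         per_class_kappa = per_class_kappa(y_true, y_pred),
         macro_auc = auc,
         errors = error_vector(decode_label(y_true), decode_label(y_pred)),
         band_true = band_histogram(decode_label(y_true)),
         band_pred = band_histogram(decode_label(y_pred))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  accuracy    %.4f\n", x$accuracy))
  cat(sprintf("  macro P/R/F1  %.4f / %.4f / %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("  kappa       %.4f (%s)\n", x$kappa, x$kappa_band))
  if (!is.na(x$macro_auc)) cat(sprintf("  macro AUC   %.4f\n", x$macro_auc))
  cat(sprintf("  mean |score error|  %.2f\n", mean(x$errors)))
  invisible(x)
}
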