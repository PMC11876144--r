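cm2 <- function() matrix(c(4L, 1L, 2L, 3L), 2, 2, byrow = TRUE)

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(0L, 0L, 1L), c(0L, 1L, 1L))
  expect_identical(cm["0", "0"], 1L)
  expect_identical(cm["0", "1"], 1L)
  expect_identical(cm["1", "1"], 1L)
  expect_identical(sum(cm), 3L)
  perfect <- confusion(0:10, 0:10)
  expect_identical(unname(diag(perfect)), rep(1L, 11))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion(0:2, 0:1), "equal length")
  expect_error(confusion(0:2, c(0L, 1L, 11L)), "0..10")
})

test_that("precision, recall, F1 and the Jaccard ratio match hand arithmetic", {
  out <- prf_macro(cm2())
  expect_equal(out$per_class$precision[1], 4 / 6)
  expect_equal(out$per_class$recall[1], 4 / 5)
  expect_equal(out$per_class$f1[1],
               2 * (4 / 6 * 4 / 5) / (4 / 6 + 4 / 5), tolerance = 1e-12)
  expect_equal(out$per_class$f1[1], 0.7273, tolerance = 1e-4)
  expect_equal(out$per_class$jaccard[1], 4 / 7)

  diag_cm <- diag(3L)
  expect_true(all(prf_macro(diag_cm)$macro == 1))
})

test_that("the per-class Jaccard ratio never exceeds precision or recall", {
  set.seed(10)
  for (i in 1:20) {
    cm <- matrix(rpois(25, 3), 5, 5)
    out <- prf_macro(cm)
    expect_true(all(out$per_class$jaccard <= out$per_class$precision + 1e-12))
    expect_true(all(out$per_class$jaccard <= out$per_class$recall + 1e-12))
  }
})

test_that("overall accuracy equals the confusion-matrix trace ratio", {
  expect_equal(overall_accuracy(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L)), 1)
  expect_equal(overall_accuracy(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 0L)), 0.75)
  set.seed(3)
  yt <- sample(0:10, 60, replace = TRUE)
  yp <- sample(0:10, 60, replace = TRUE)
  cm <- confusion(yt, yp)
  expect_equal(overall_accuracy(yt, yp), sum(diag(cm)) / sum(cm))
  expect_error(overall_accuracy(integer(0), integer(0)), "no samples")
})

test_that("Cohen's kappa matches the hand-worked example and edge cases", {
  expect_equal(cohen_kappa(diag(5L) * 3L), 1)
  # [[4,1],[2,3]]: p_o = 0.7, p_e = (5*6 + 5*4) / 100 = 0.5 -> kappa 0.4
  expect_equal(cohen_kappa(cm2()), 0.4, tolerance = 1e-12)
  # kappa = 0 when observed equals chance agreement
  cm_indep <- matrix(c(4L, 4L, 1L, 1L), 2, 2)
  expect_equal(cohen_kappa(cm_indep), 0)
  # kappa = 1 iff the matrix is diagonal
  expect_lt(cohen_kappa(matrix(c(9L, 1L, 0L, 9L), 2, 2)), 1)
  # undefined when all mass sits in a single row and column
  one_cell <- matrix(0L, 2, 2)
  one_cell[1, 1] <- 5L
  expect_warning(k <- cohen_kappa(one_cell), "undefined")
  expect_true(is.na(k))
})

test_that("kappa bands follow the six-level verbal scale", {
  expect_identical(kappa_band(0.9), "almost perfect agreement")
  expect_identical(kappa_band(0.81), "almost perfect agreement")
  expect_identical(kappa_band(0.80), "significant agreement")
  expect_identical(kappa_band(0.61), "significant agreement")
  expect_identical(kappa_band(0.41), "moderate agreement")
  expect_identical(kappa_band(0.21), "fair agreement")
  expect_identical(kappa_band(0), "very low agreement")
  expect_identical(kappa_band(-0.2), "no or very poor agreement")
})

test_that("per-class one-vs-rest kappa collapses to the binary case", {
  # realise cm [[4,1],[2,3]] on classes {0, 1}
  yt <- c(rep(0L, 5), rep(1L, 5))
  yp <- c(rep(0L, 4), 1L, 0L, 0L, 1L, 1L, 1L)
  pk <- per_class_kappa(yt, yp)
  expect_equal(unname(pk["0"]), 0.4, tolerance = 1e-12)
  expect_true(is.na(pk["5"]))
  perfect <- per_class_kappa(0:10, 0:10)
  expect_true(all(perfect == 1))
})

test_that("rank-statistic AUC agrees with exhaustive pair counting", {
  # 4-sample toys: perfect ranking, then one discordant pair (3 of 4)
  expect_equal(talsrx:::auc_rank(c(0.9, 0.8), c(0.7, 0.6)), 1)
  expect_equal(talsrx:::auc_rank(c(0.9, 0.7), c(0.8, 0.6)), 0.75)
  # all-ties
  expect_equal(talsrx:::auc_rank(rep(0.5, 3), rep(0.5, 4)), 0.5)
  # oracle equivalence on random instances with ties, n <= 50
  set.seed(8)
  for (i in 1:25) {
    n_pos <- sample(2:25, 1)
    n_neg <- sample(2:25, 1)
    pos <- round(runif(n_pos), 1) # coarse rounding forces ties
    neg <- round(runif(n_neg), 1)
    expect_equal(talsrx:::auc_rank(pos, neg), auc_pairs(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("macro one-vs-rest AUC behaves at the extremes", {
  y <- c(0L, 0L, 1L, 1L)
  P_perfect <- matrix(0, 4, 11)
  P_perfect[1:2, 1] <- 0.9
  P_perfect[3:4, 2] <- 0.9
  P_perfect[1:2, 2] <- 0.1
  P_perfect[3:4, 1] <- 0.1
  expect_equal(ovr_macro_auc(y, P_perfect), 1)
  P_flat <- matrix(1 / 11, 4, 11)
  expect_equal(ovr_macro_auc(y, P_flat), 0.5)
  expect_error(ovr_macro_auc(rep(1L, 4), P_flat), "single class")
})

test_that("macro F1 is invariant under class relabelling", {
  set.seed(4)
  yt <- sample(0:5, 80, replace = TRUE)
  yp <- sample(0:5, 80, replace = TRUE)
  perm <- sample(0:10)
  m1 <- prf_macro(confusion(yt, yp))$macro
  m2 <- prf_macro(confusion(perm[yt + 1L], perm[yp + 1L]))$macro
  expect_equal(m2, m1, tolerance = 1e-12)
})

test_that("score errors and band histograms conserve mass", {
  expect_identical(error_vector(100L, 90L), 10L)
  expect_identical(error_vector(c(0L, 50L), c(0L, 50L)), c(0L, 0L))
  expect_error(error_vector(15L, 10L), "multiple of 10")
  scores <- decode_label(sample(0:10, 40, replace = TRUE))
  h <- band_histogram(scores)
  expect_identical(sum(h), 40L)
  expect_length(h, 11)
  # perfect predictions: zero errors, identical histograms
  expect_identical(band_histogram(scores), band_histogram(scores))
  expect_true(all(error_vector(scores, scores) == 0))
})

test_that("evaluation reports assemble all components coherently", {
  set.seed(12)
  y <- sample(0:10, 80, replace = TRUE)
  P <- matrix(runif(80 * 11), 80)
  P <- P / rowSums(P)
  P[cbind(1:80, y + 1)] <- P[cbind(1:80, y + 1)] + 1.2 # informative signal
  P <- P / rowSums(P)
  rep <- eval_report(y, P)
  expect_s3_class(rep, "eval_report")
  expect_identical(sum(rep$confusion), 80L)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 80)
  expect_true(rep$kappa >= -1 && rep$kappa <= 1)
  expect_true(all(rep$errors %% 10 == 0))
  expect_identical(sum(rep$band_pred), 80L)
  expect_gt(rep$macro_auc, 0.5)
})
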