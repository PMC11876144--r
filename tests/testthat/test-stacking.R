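test_that("out-of-fold meta-features have the stacked shape and fold structure", {
  dat <- small_plate_data()
  oof <- oof_meta_features(dat$X, dat$y, k = 5, seed = 2,
                           base_fitters = list(svm = fit_freq_probe,
                                               rf = fit_freq_probe))
  expect_identical(dim(oof$Z), c(nrow(dat$X), 22L))
  f <- oof$fold_assignments
  expect_setequal(unique(f), 1:5)
  # near-equal disjoint partition
  expect_lte(diff(range(table(f))), 1)
  expect_length(f, nrow(dat$X))
})

test_that("every OOF row equals the class distribution of its training folds", {
  dat <- small_plate_data()
  oof <- oof_meta_features(dat$X, dat$y, k = 5, seed = 2,
                           base_fitters = list(svm = fit_freq_probe,
                                               rf = fit_freq_probe))
  for (j in 1:5) {
    expected <- tabulate(dat$y[oof$fold_assignments != j] + 1L, 11L)
    expected <- expected / sum(expected)
    rows <- which(oof$fold_assignments == j)
    for (i in rows) {
      expect_equal(unname(oof$Z[i, 1:11]), expected, tolerance = 1e-12)
      expect_equal(unname(oof$Z[i, 12:22]), expected, tolerance = 1e-12)
    }
  }
})

test_that("OOF rows are leak-free: a sample's own fold is untouched by its change", {
  dat <- small_plate_data()
  fitters <- list(svm = fit_freq_probe, rf = fit_freq_probe)
  oof1 <- oof_meta_features(dat$X, dat$y, k = 5, seed = 2,
                            base_fitters = fitters)
  i <- 1L
  f_i <- oof1$fold_assignments[i]
  y2 <- dat$y
  y2[i] <- (y2[i] + 5L) %% 11L # change one training label
  oof2 <- oof_meta_features(dat$X, y2, k = 5, seed = 2,
                            base_fitters = fitters,
                            fold = oof1$fold_assignments)
  own <- oof1$fold_assignments == f_i
  # rows of the sample's own fold come from models that never saw it
  expect_identical(oof1$Z[own, ], oof2$Z[own, ])
  # rows of every other fold come from models trained on it, so they move
  expect_false(isTRUE(all.equal(oof1$Z[!own, ], oof2$Z[!own, ])))
})

test_that("row order permutation permutes the OOF rows with it", {
  dat <- small_plate_data()
  fitters <- list(svm = fit_freq_probe, rf = fit_freq_probe)
  oof1 <- oof_meta_features(dat$X, dat$y, k = 5, seed = 2,
                            base_fitters = fitters)
  set.seed(99)
  perm <- sample(nrow(dat$X))
  oof2 <- oof_meta_features(dat$X[perm, ], dat$y[perm], k = 5, seed = 2,
                            base_fitters = fitters,
                            fold = oof1$fold_assignments[perm])
  expect_equal(oof2$Z, oof1$Z[perm, ], tolerance = 1e-12)
})

test_that("a fold missing a class pads its probability with zero", {
  blobs <- make_blobs(n_per = 20, p = 4, sep = 6, seed = 3,
                      classes = c(1L, 8L))
  # force all class-1 samples into fold 1's complement so fold-2 models
  # never see class 8
  fold <- c(rep(1L, 20), rep(2L, 20))
  suppressWarnings(
    oof <- oof_meta_features(blobs$X, blobs$y, k = 2, seed = 1, fold = fold))
  # fold-1 rows were predicted by a model trained only on class 8
  expect_true(all(oof$Z[fold == 1L, "svm_p8"] == 1))
  expect_true(all(oof$Z[fold == 1L, "svm_p1"] == 0))
})

test_that("the stacked model trains, predicts and reproduces", {
  dat <- small_plate_data()
  suppressWarnings({
    st1 <- fit_stack(dat$X, dat$y, tune = FALSE, seed = 5)
    st2 <- fit_stack(dat$X, dat$y, tune = FALSE, seed = 5)
  })
  expect_named(st1$base_models, c("svm", "rf"))
  expect_identical(st1$base_models$svm$kind, "svm")
  expect_identical(st1$base_models$rf$kind, "rf")
  expect_identical(st1$meta_model$kind, "xgb")

  P1 <- predict_proba(st1, dat$X)
  P2 <- predict_proba(st2, dat$X)
  expect_identical(P1, P2)
  expect_true(all(abs(rowSums(P1) - 1) < 1e-9))
  # better than chance on its own training distribution
  expect_gt(mean(predict(st1, dat$X, type = "class") == dat$y), 1 / 11)
  # single-row input gives single-row output
  expect_identical(dim(predict_proba(st1, dat$X[1, , drop = FALSE])),
                   c(1L, 11L))
  expect_error(predict_proba(st1, dat$X[, 1:100]), "192")
})

test_that("stacking separates the extreme rubric classes perfectly", {
  counts <- c("100" = 50, "0" = 50)
  train <- generate_dataset(counts, seed = 21, jitter = 0)
  # held-out plates: noiseless ideal class-100 geometry vs fully diffuse
  # class-0 clouds -- maximal separation by construction
  test <- kasp_dataset(c(
    lapply(1:25, function(s) sample_plate(zero_noise_spec(100), seed = 1000 + s)),
    lapply(1:25, function(s) sample_plate(default_spec(0), seed = 2000 + s))))
  suppressWarnings(
    st <- fit_stack(feature_matrix(train),
                    encode_label(dataset_labels(train)), seed = 2))
  pred <- predict(st, test, type = "class")
  expect_identical(pred, encode_label(dataset_labels(test)))
})
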