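# Fixtures built in code: tiny plates, Gaussian blobs, probe learners.

# a plate with three point clusters at given centroids (no noise) and the
# NTC wells at a fixed background spot; counts follow the 40/40/14 default
point_plate <- function(cAA, cBB, cAB, ntc = c(0.3, 0.3), snp_id = "FIX") {
  xy <- rbind(
    matrix(rep(cAA, each = 40), 40),
    matrix(rep(cBB, each = 40), 40),
    matrix(rep(cAB, each = 14), 14),
    matrix(rep(ntc, each = 2), 2))
  kasp_plate(snp_id,
             data.frame(x = xy[, 1], y = xy[, 2],
                        role = c(rep("DNA", 94), rep("NTC", 2)),
                        genotype = c(rep("AA", 40), rep("BB", 40),
                                     rep("AB", 14), "unknown", "unknown")),
             label = 100L)
}

# near-noiseless morphology spec for a rubric class
zero_noise_spec <- function(score) {
  spec <- default_spec(score)
  spec$cluster_sd <- 1e-9
  spec
}

# two well-separated Gaussian blobs in p dimensions
make_blobs <- function(n_per = 50, p = 6, sep = 6, sd = 1, seed = 1,
                       classes = c(0L, 1L)) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
             matrix(rnorm(n_per * p, sep, sd), n_per))
  list(X = X, y = rep(classes, each = n_per))
}

# small labelled synthetic plate set shared across tests
small_plate_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_dataset(stats::setNames(rep(10, 11), seq(0, 100, 10)),
                            seed = 11)
      cache <<- list(X = feature_matrix(d),
                     y = encode_label(dataset_labels(d)),
                     dataset = d)
    }
    cache
  }
})

# probe learner predicting its training-set class frequencies for every row
fit_freq_probe <- function(X, y, seed) {
  structure(list(freq = tabulate(y + 1L, nbins = 11L) / length(y)),
            class = "freq_probe")
}
predict_proba.freq_probe <- function(object, X, ...) {
  matrix(object$freq, nrow(X), 11, byrow = TRUE,
         dimnames = list(NULL, as.character(0:10)))
}
registerS3method("predict_proba", "freq_probe", predict_proba.freq_probe,
                 envir = asNamespace("talsrx"))

# exhaustive pair-counting AUC oracle (ties count one half)
auc_pairs <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}
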