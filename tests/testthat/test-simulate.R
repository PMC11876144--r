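test_that("default class specs realise the rubric clauses", {
  s100 <- default_spec(100)
  expect_equal(s100$het_centroid,
               (s100$hom_A_centroid + s100$hom_B_centroid) / 2)
  expect_identical(default_spec(10)$ntc_mode, "specific")
  expect_gt(default_spec(90)$het_offset_perp, 0)
  expect_gt(default_spec(80)$het_shift_along, 0)
  expect_identical(default_spec(70)$hom_affected, "A")
  expect_gt(default_spec(70)$hom_shift, 0)
  expect_gt(default_spec(70, trailing = TRUE)$tail_scale, 0)
  expect_gt(default_spec(60)$hom_shift, 0)
  expect_gt(default_spec(50)$tail_scale, 0)
  expect_gt(default_spec(0)$diffusion_factor,
            default_spec(100)$diffusion_factor)
  expect_error(default_spec(55), "multiple of 10")
})

test_that("zero-noise class-100 plates collapse to the ideal geometry", {
  p <- sample_plate(zero_noise_spec(100), seed = 1)
  g <- morphology_descriptors(p)
  expect_equal(unname(g$het_midpoint_deviation), c(0, 0), tolerance = 1e-6)
  expect_lt(max(unlist(g$within_spread)), 1e-6)
  # het wells sit exactly at the homozygote midpoint in the noiseless limit
  het <- p$wells[p$wells$genotype == "AB", ]
  expect_equal(unique(round(het$x, 6)), 0.815)
  expect_equal(unique(round(het$y, 6)), 0.815)
})

test_that("simulated signals stay in the observed relative range", {
  p <- sample_plate(default_spec(100), seed = 1)
  expect_true(all(p$wells$x >= 0 & p$wells$x <= 1.6))
  expect_true(all(p$wells$y >= 0 & p$wells$y <= 1.6))
})

test_that("NTC specificity flags exactly the class-10 morphology", {
  idx <- vapply(seq(0, 100, 10), function(s) {
    morphology_descriptors(sample_plate(default_spec(s),
                                        seed = 1))$ntc_specificity_index
  }, numeric(1))
  names(idx) <- seq(0, 100, 10)
  expect_gt(idx[["10"]], ntc_specificity_threshold())
  expect_true(all(idx[names(idx) != "10"] < ntc_specificity_threshold()))
  expect_gt(idx[["10"]],
            morphology_descriptors(sample_plate(default_spec(100),
                                                seed = 1))$ntc_specificity_index)
})

test_that("separation decreases along the diffusion-driven classes", {
  sep <- vapply(c(100, 40, 30, 20, 0), function(s) {
    morphology_descriptors(sample_plate(default_spec(s),
                                        seed = 7))$separation_index
  }, numeric(1))
  expect_true(all(diff(sep) < 0))
})

test_that("generated datasets have the requested composition and are reproducible", {
  d <- generate_dataset(c("100" = 5, "0" = 5), seed = 4)
  expect_length(d, 10)
  expect_identical(as.vector(table(dataset_labels(d))), c(5L, 5L))
  d2 <- generate_dataset(c("100" = 5, "0" = 5), seed = 4)
  expect_identical(feature_matrix(d), feature_matrix(d2))
  expect_length(generate_dataset(stats::setNames(integer(0), character(0))), 0)
  counts <- stats::setNames(rep(3, 11), seq(0, 100, 10))
  d3 <- generate_dataset(counts, seed = 4)
  expect_length(d3, 33)
  expect_length(unique(dataset_labels(d3)), 11)
})

test_that("descriptor geometry follows a hand-worked oracle", {
  # horizontal homozygote line so the parallel direction stays along x:
  # shifting the AA cluster +0.2 in x moves the midpoint by +0.1 while the
  # het centroid stays put -> deviation of magnitude 0.1, purely parallel
  base <- point_plate(cAA = c(0.4, 0.33), cBB = c(1.2, 0.33),
                      cAB = c(0.8, 0.33))
  g0 <- morphology_descriptors(base)
  expect_equal(unname(g0$het_midpoint_deviation), c(0, 0), tolerance = 1e-12)
  shifted <- point_plate(cAA = c(0.6, 0.33), cBB = c(1.2, 0.33),
                         cAB = c(0.8, 0.33))
  g1 <- morphology_descriptors(shifted)
  expect_equal(abs(unname(g1$het_midpoint_deviation[1])), 0.1,
               tolerance = 1e-12)
  expect_equal(unname(g1$het_midpoint_deviation[2]), 0, tolerance = 1e-12)
})

test_that("descriptors are invariant under allele relabelling with axis swap", {
  p <- sample_plate(default_spec(50), seed = 9)
  w <- p$wells
  swap <- c(AA = "BB", BB = "AA", AB = "AB", unknown = "unknown")
  w2 <- data.frame(x = w$y, y = w$x, role = w$role,
                   genotype = unname(swap[w$genotype]))
  p2 <- kasp_plate(p$snp_id, w2, label = p$label)
  g <- morphology_descriptors(p)
  g2 <- morphology_descriptors(p2)
  expect_equal(g2$separation_index, g$separation_index, tolerance = 1e-12)
  expect_equal(g2$ntc_specificity_index, g$ntc_specificity_index,
               tolerance = 1e-12)
  expect_equal(g2$within_spread$AA, g$within_spread$BB, tolerance = 1e-12)
  expect_equal(g2$tailing_index$BB, g$tailing_index$AA, tolerance = 1e-12)
  expect_equal(abs(g2$het_midpoint_deviation), abs(g$het_midpoint_deviation),
               tolerance = 1e-12)
})

test_that("trailing tails skew homozygote clusters towards the origin", {
  g_tail <- morphology_descriptors(sample_plate(default_spec(50), seed = 5))
  g_clean <- morphology_descriptors(sample_plate(default_spec(100), seed = 5))
  expect_gt(g_tail$tailing_index$AA, g_clean$tailing_index$AA)
  expect_gt(g_tail$tailing_index$AA, 1)
})

test_that("a genotype class with no wells is omitted from the report", {
  spec <- default_spec(100)
  spec$n_AB <- 0L
  spec$n_AA <- 47L
  spec$n_BB <- 47L
  g <- morphology_descriptors(sample_plate(spec, seed = 2))
  expect_null(g$centroids$AB)
  expect_null(g$het_midpoint_deviation)
  expect_false(is.na(g$separation_index))
})

test_that("descriptor features separate class 100 from class 0 perfectly", {
  feats <- function(score, seeds) {
    t(vapply(seeds, function(s) {
      g <- morphology_descriptors(sample_plate(default_spec(score), seed = s))
      c(sep = g$separation_index, ntc = g$ntc_specificity_index,
        spread = mean(unlist(g$within_spread)))
    }, numeric(3)))
  }
  X <- rbind(feats(100, 1:50), feats(0, 1:50))
  y <- rep(c(1L, 0L), each = 50)
  fit <- ranger::ranger(x = X, y = factor(y), num.trees = 50,
                        num.threads = 1, seed = 1)
  expect_equal(mean(as.integer(as.character(fit$predictions)) == y), 1)
})
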