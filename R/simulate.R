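#' Morphology specification for one score class
#'
#' The 0-100 typing-effect rubric grades a plate's two-channel scatter by the
#' geometry of its three genotype clusters (homozygous allele 1 `AA`, high
#' HEX; homozygous allele 2 `BB`, high FAM; heterozygous `AB`) and the
#' behaviour of the two no-template controls. A `morphology_spec` collects
#' the generative parameters that realise one rubric class:
#'
#' * `hom_A_centroid`, `hom_B_centroid`: ideal cluster centres, defaulting to
#'   the axis maxima `(hi, bg)` and `(bg, hi)`.
#' * `cluster_sd`: isotropic within-cluster spread; `diffusion_factor`
#'   multiplies it (diffuse, hard-to-type classes).
#' * `het_offset_perp`, `het_shift_along`: displacement of the heterozygous
#'   centroid perpendicular to / along the line joining the homozygote
#'   centroids (classes 90 and 80).
#' * `hom_shift`: displacement of homozygote centroid(s) along their high
#'   axis towards the origin (classes 70 and 60); `hom_affected` says whether
#'   one (`"A"`) or both (`"both"`) homozygotes move.
#' * `tail_scale`, `tail_fraction`: exponential elongation of homozygote
#'   clusters towards the origin ("trailing tail", class 50).
#' * `ntc_mode`: `"background"` (controls sit at background signal) or
#'   `"specific"` (controls amplify into the signal range, class 10).
#'
#' Signal levels default to background 0.33 and high 1.30, the magnitudes of
#' relative HEX/FAM readouts on real plates (observed range roughly
#' 0.28-1.43).
#'
#' @param score rubric score, a multiple of 10 in `[0, 100]`.
#' @param trailing for score 70, use the trailing-tail variant of the rubric
#'   clause ("one pure genotype is shifted or trailing") instead of the
#'   default shift.
#' @param bg,hi background and high signal levels.
#' @return an object of class `morphology_spec`.
#' @export
default_spec <- function(score, trailing = FALSE, bg = 0.33, hi = 1.30) {
  check_score(score)
  stopifnot(length(score) == 1L)
  spec <- list(
    score = as.integer(score),
    n_AA = 40L, n_BB = 40L, n_AB = 14L,
    hom_A_centroid = c(hi, bg),
    hom_B_centroid = c(bg, hi),
    cluster_sd = 0.035,
    het_offset_perp = 0,
    het_shift_along = 0,
    hom_shift = 0,
    hom_affected = "both",
    tail_scale = 0,
    tail_fraction = 0.4,
    diffusion_factor = 1,
    ntc_mode = "background",
    bg = bg, hi = hi)
  if (score == 90L) {
    spec$het_offset_perp <- 0.18
  } else if (score == 80L) {
    spec$het_shift_along <- 0.22
  } else if (score == 70L) {
    if (trailing) spec$tail_scale <- 0.35 else spec$hom_shift <- 0.28
    spec$hom_affected <- "A"
  } else if (score == 60L) {
    spec$hom_shift <- 0.22
  } else if (score == 50L) {
    spec$tail_scale <- 0.30
  } else if (score == 40L) {
    spec$diffusion_factor <- 2.2
    spec$hom_shift <- 0.10
  } else if (score == 30L) {
    spec$diffusion_factor <- 3.2
    spec$het_shift_along <- 0.15
  } else if (score == 20L) {
    spec$diffusion_factor <- 5
  } else if (score == 10L) {
    spec$ntc_mode <- "specific"
  } else if (score == 0L) {
    spec$diffusion_factor <- 8
  }
  spec$het_centroid <- effective_centroids(spec)$het
  structure(spec, class = "morphology_spec")
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "morphology_spec"))
  if (spec$n_AA + spec$n_BB + spec$n_AB != 94L) {
    stop_talsrx("genotype counts must sum to 94 DNA wells")
  }
  if (spec$cluster_sd <= 0) stop_talsrx("cluster_sd must be > 0")
  if (spec$diffusion_factor < 1) stop_talsrx("diffusion_factor must be >= 1")
  if (!spec$ntc_mode %in% c("background", "specific")) {
    stop_talsrx("ntc_mode must be 'background' or 'specific'")
  }
  check_score(spec$score)
  invisible(spec)
}

# centroids after shifts: homozygote shift moves the high-axis coordinate
# towards the origin; the het centroid is the midpoint of the (shifted)
# homozygote line plus its along/perpendicular offsets
effective_centroids <- function(spec) {
  cA <- spec$hom_A_centroid
  cB <- spec$hom_B_centroid
  if (spec$hom_shift > 0) {
    if (spec$hom_affected %in% c("A", "both")) cA[1] <- cA[1] - spec$hom_shift
    if (spec$hom_affected == "both")           cB[2] <- cB[2] - spec$hom_shift
  }
  mid <- (cA + cB) / 2
  u <- cB - cA
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0)
  vperp <- c(-u[2], u[1])
  het <- mid + spec$het_shift_along * u + spec$het_offset_perp * vperp
  list(hom_A = cA, hom_B = cB, het = het, along = u, perp = vperp)
}

#' @export
print.morphology_spec <- function(x, ...) {
  cat(sprintf("<morphology_spec> score %d\n", x$score))
  cat(sprintf("  wells AA/BB/AB: %d/%d/%d  cluster_sd %.3f  diffusion x%.1f\n",
              x$n_AA, x$n_BB, x$n_AB, x$cluster_sd, x$diffusion_factor))
  cat(sprintf("  het offsets (along %.2f, perp %.2f)  hom_shift %.2f (%s)  tail %.2f\n",
              x$het_shift_along, x$het_offset_perp, x$hom_shift,
              x$hom_affected, x$tail_scale))
  cat(sprintf("  NTC mode: %s\n", x$ntc_mode))
  invisible(x)
}

#' Simulate one KASP plate from a morphology specification
#'
#' DNA wells are drawn per genotype as centroid plus isotropic Gaussian noise
#' of standard deviation `cluster_sd * diffusion_factor`. When
#' `tail_scale > 0`, a `tail_fraction` of each affected homozygote cluster is
#' displaced towards the origin by an exponential distance of mean
#' `tail_scale` (the "trailing tail"). The two NTC wells sit at the
#' background point unless `ntc_mode = "specific"`, in which case they
#' amplify into the signal range. DNA well order is shuffled so well position
#' carries no genotype information, as on real plates. Coordinates are
#' truncated at zero (fluorescence is non-negative).
#'
#' @param spec a [default_spec()] or modified `morphology_spec`.
#' @param seed integer seed.
#' @param snp_id identifier for the simulated assay.
#' @return a [kasp_plate()] with genotype assignments and `label = spec$score`.
#' @export
sample_plate <- function(spec, seed = 1L, snp_id = sprintf("SIM%03d", spec$score)) {
  validate_spec(spec)
  set.seed(seed)
  cen <- effective_centroids(spec)
  sd_eff <- spec$cluster_sd * spec$diffusion_factor
  draw_cluster <- function(n, centroid, tailed) {
    if (n == 0L) return(matrix(numeric(0), ncol = 2))
    pts <- cbind(stats::rnorm(n, centroid[1], sd_eff),
                 stats::rnorm(n, centroid[2], sd_eff))
    if (tailed && spec$tail_scale > 0) {
      n_tail <- round(n * spec$tail_fraction)
      if (n_tail > 0) {
        idx <- sample.int(n, n_tail)
        nc <- sqrt(sum(centroid^2))
        dir <- if (nc > 0) -centroid / nc else c(0, 0)
        d <- stats::rexp(n_tail, rate = 1 / spec$tail_scale)
        pts[idx, ] <- pts[idx, ] + d %o% dir
      }
    }
    pts
  }
  tail_A <- spec$hom_affected %in% c("A", "both")
  tail_B <- spec$hom_affected == "both"
  dna <- rbind(draw_cluster(spec$n_AA, cen$hom_A, tail_A),
               draw_cluster(spec$n_BB, cen$hom_B, tail_B),
               draw_cluster(spec$n_AB, cen$het, FALSE))
  geno <- c(rep("AA", spec$n_AA), rep("BB", spec$n_BB), rep("AB", spec$n_AB))
  ord <- sample.int(94L)
  dna <- dna[ord, , drop = FALSE]
  geno <- geno[ord]
  ntc_centre <- if (spec$ntc_mode == "specific") {
    c(spec$bg + 0.55 * (spec$hi - spec$bg), spec$bg + 0.55 * (spec$hi - spec$bg))
  } else {
    c(spec$bg * 0.92, spec$bg * 0.92)
  }
  ntc_sd <- if (spec$ntc_mode == "specific") 0.04 else 0.015
  ntc <- cbind(stats::rnorm(2, ntc_centre[1], ntc_sd),
               stats::rnorm(2, ntc_centre[2], ntc_sd))
  xy <- rbind(dna, ntc)
  xy[xy < 0] <- 0
  kasp_plate(snp_id,
             data.frame(x = xy[, 1], y = xy[, 2],
                        role = c(rep("DNA", 94), rep("NTC", 2)),
                        genotype = c(geno, "unknown", "unknown")),
             label = spec$score)
}

# perturb numeric morphology parameters within +/- jitter of their defaults,
# respecting hard floors (sd > 0, diffusion >= 1)
jitter_spec <- function(spec, jitter = 0.2) {
  if (jitter <= 0) return(spec)
  j <- function(v) v * stats::runif(length(v), 1 - jitter, 1 + jitter)
  spec$hom_A_centroid <- j(spec$hom_A_centroid)
  spec$hom_B_centroid <- j(spec$hom_B_centroid)
  spec$cluster_sd <- max(j(spec$cluster_sd), 1e-4)
  spec$het_offset_perp <- j(spec$het_offset_perp)
  spec$het_shift_along <- j(spec$het_shift_along)
  spec$hom_shift <- j(spec$hom_shift)
  spec$tail_scale <- j(spec$tail_scale)
  spec$tail_fraction <- min(j(spec$tail_fraction), 1)
  spec$diffusion_factor <- max(j(spec$diffusion_factor), 1)
  counts <- round(j(c(spec$n_AA, spec$n_BB, spec$n_AB)))
  counts <- pmax(counts, 1L)
  while (sum(counts) != 94L) { # repair rounding drift one well at a time
    i <- which.max(counts)
    if (sum(counts) > 94L) counts[i] <- counts[i] - 1L
    else counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  }
  spec$n_AA <- counts[1]; spec$n_BB <- counts[2]; spec$n_AB <- counts[3]
  spec
}

#' Generate a labelled synthetic dataset
#'
#' Draws `class_counts[s]` plates for each requested score class. Each plate
#' gets its own jittered copy of the class default spec (numeric parameters
#' perturbed within +/-20 percent) so a class has internal variation, and its
#' own seed derived from `seed`, making the dataset reproducible.
#'
#' @param class_counts named vector: names are scores, values are counts,
#'   e.g. `c("100" = 5, "0" = 5)`.
#' @param seed integer root seed.
#' @param jitter relative jitter applied to spec parameters (0 disables).
#' @param trailing passed to [default_spec()].
#' @return a [kasp_dataset()].
#' @examples
#' d <- generate_dataset(c("100" = 3, "0" = 3), seed = 1)
#' table(dataset_labels(d))
#' @export
generate_dataset <- function(class_counts, seed = 1L, jitter = 0.2,
                             trailing = FALSE) {
  if (length(class_counts) == 0L) return(kasp_dataset(list()))
  scores <- as.integer(names(class_counts))
  check_score(scores)
  if (any(class_counts < 0)) stop_talsrx("class counts must be >= 0")
  records <- list()
  k <- 0L
  for (i in seq_along(scores)) {
    base <- default_spec(scores[i], trailing = trailing)
    for (r in seq_len(class_counts[i])) {
      k <- k + 1L
      s <- derive_seed(seed, k)
      set.seed(s)
      spec <- jitter_spec(base, jitter)
      records[[k]] <- sample_plate(spec, seed = derive_seed(s, 1L),
                                   snp_id = sprintf("SIM%03d_%04d", scores[i], r))
    }
  }
  kasp_dataset(records)
}
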