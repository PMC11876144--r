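#' Geometric morphology descriptors of a plate
#'
#' Quantifies the cluster geometry that the 0-100 rubric describes verbally.
#' Requires genotype assignments (simulator output or externally called
#' plates). Per genotype cluster present on the plate:
#'
#' * `centroids`: mean (x, y) per genotype.
#' * `within_spread`: root-mean-square distance of cluster points to their
#'   centroid.
#' * `het_midpoint_deviation`: signed (parallel, perpendicular) components of
#'   the heterozygote centroid minus the homozygote midpoint, taken along the
#'   line joining the homozygote centroids; `(0, 0)` when the heterozygotes
#'   sit exactly at the midpoint.
#' * `tailing_index`: skewness of the projections of each homozygote cluster
#'   onto its centroid-to-origin direction; trailing tails give positive
#'   values.
#' * `separation_index`: minimum inter-centroid distance divided by the mean
#'   within-cluster spread (`Inf` for noiseless plates); diffuse classes
#'   score low.
#' * `ntc_specificity_index`: maximum NTC distance from the estimated
#'   background point divided by the mean distance of the genotype centroids
#'   from it; values near or above 1 indicate amplification in the controls.
#'   The background point is estimated as the per-axis 10th percentile of the
#'   DNA wells.
#'
#' All indices are ratios of distances, so they are invariant under a common
#' rescaling of both channels.
#'
#' @param plate a [kasp_plate()] with genotype assignments.
#' @return an object of class `geometry_report` (a list of the fields above).
#' @export
morphology_descriptors <- function(plate) {
  validate_plate(plate)
  w <- plate$wells
  dna <- w[w$role == "DNA", ]
  ntc <- w[w$role == "NTC", ]
  genos <- intersect(c("AA", "BB", "AB"), unique(dna$genotype))
  if (length(genos) == 0L) {
    stop_talsrx("plate '%s': no genotype assignments; descriptors need simulator output or called plates",
                plate$snp_id)
  }
  centroids <- list()
  spread <- list()
  for (g in genos) {
    pts <- as.matrix(dna[dna$genotype == g, c("x", "y")])
    cen <- colMeans(pts)
    centroids[[g]] <- cen
    spread[[g]] <- sqrt(mean((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2))
  }
  het_dev <- NULL
  if (all(c("AA", "BB", "AB") %in% genos)) {
    mid <- (centroids$AA + centroids$BB) / 2
    u <- centroids$BB - centroids$AA
    nu <- sqrt(sum(u^2))
    u <- if (nu > 0) u / nu else c(1, 0)
    vperp <- c(-u[2], u[1])
    d <- centroids$AB - mid
    het_dev <- c(parallel = sum(d * u), perpendicular = sum(d * vperp))
  }
  tailing <- list()
  for (g in intersect(c("AA", "BB"), genos)) {
    pts <- as.matrix(dna[dna$genotype == g, c("x", "y")])
    cen <- centroids[[g]]
    nc <- sqrt(sum(cen^2))
    dir <- if (nc > 0) -cen / nc else c(1, 0)
    t_proj <- (pts[, 1] - cen[1]) * dir[1] + (pts[, 2] - cen[2]) * dir[2]
    m2 <- mean((t_proj - mean(t_proj))^2)
    m3 <- mean((t_proj - mean(t_proj))^3)
    tailing[[g]] <- if (m2 > 0) m3 / m2^1.5 else 0
  }
  sep <- NA_real_
  if (length(genos) >= 2L) {
    cm <- do.call(rbind, centroids)
    dists <- stats::dist(cm)
    mean_spread <- mean(unlist(spread))
    sep <- if (mean_spread > 0) min(dists) / mean_spread else Inf
  }
  bg_point <- c(stats::quantile(dna$x, 0.1, names = FALSE),
                stats::quantile(dna$y, 0.1, names = FALSE))
  ntc_dist <- sqrt((ntc$x - bg_point[1])^2 + (ntc$y - bg_point[2])^2)
  cen_dist <- vapply(centroids, function(cen) sqrt(sum((cen - bg_point)^2)),
                     numeric(1))
  ntc_idx <- if (mean(cen_dist) > 0) max(ntc_dist) / mean(cen_dist) else Inf
  structure(
    list(centroids = centroids,
         within_spread = spread,
         het_midpoint_deviation = het_dev,
         tailing_index = tailing,
         separation_index = sep,
         ntc_specificity_index = ntc_idx,
         background_point = bg_point),
    class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>\n")
  for (g in names(x$centroids)) {
    cat(sprintf("  %s: centroid (%.3f, %.3f), spread %.4f\n", g,
                x$centroids[[g]][1], x$centroids[[g]][2], x$within_spread[[g]]))
  }
  if (!is.null(x$het_midpoint_deviation)) {
    cat(sprintf("  het midpoint deviation: along %.4f, perp %.4f\n",
                x$het_midpoint_deviation[1], x$het_midpoint_deviation[2]))
  }
  cat(sprintf("  separation index: %.3f   NTC specificity index: %.3f\n",
              x$separation_index, x$ntc_specificity_index))
  invisible(x)
}

#' Threshold on the NTC specificity index
#'
#' Default plates of every class except score 10 keep their controls at
#' background, giving indices well below this threshold; the specific-NTC
#' class exceeds it.
#'
#' @return a scalar threshold.
#' @export
ntc_specificity_threshold <- function() 0.5
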