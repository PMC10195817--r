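# Coordinate-based degree-of-colocalization (DoC) scoring between two
# localization channels, after the ClusDoC construction: local density
# gradients across a radius ladder, rank-correlated between channels and
# damped by the nearest-neighbour distance to the other channel.

# Neighbour counts of `query` points among `ref` points at each radius.
# exclude_self drops one zero-distance match per query (same-channel case).
radial_counts <- function(qx, qy, rx, ry, radii, exclude_self = FALSE) {
  nq <- length(qx); nr <- length(radii)
  counts <- matrix(0L, nq, nr)
  chunk <- 512L
  for (s in seq(1, nq, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nq)
    d <- sqrt(outer(qx[idx], rx, `-`)^2 + outer(qy[idx], ry, `-`)^2)
    if (exclude_self) d[cbind(seq_along(idx), idx)] <- Inf
    bins <- matrix(findInterval(d, radii, left.open = TRUE), nrow(d))
    for (k in seq_along(idx)) {
      tab <- tabulate(bins[k, ] + 1L, nbins = nr + 1L)
      counts[idx[k], ] <- cumsum(tab)[seq_len(nr)]
    }
  }
  counts
}

nearest_cross_distance <- function(qx, qy, rx, ry) {
  nq <- length(qx)
  out <- numeric(nq)
  chunk <- 512L
  for (s in seq(1, nq, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nq)
    d2 <- outer(qx[idx], rx, `-`)^2 + outer(qy[idx], ry, `-`)^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

doc_scores_one_channel <- function(self, other, radii) {
  r_max <- radii[length(radii)]
  n_self <- radial_counts(self$x, self$y, self$x, self$y, radii,
                          exclude_self = TRUE)
  n_other <- radial_counts(self$x, self$y, other$x, other$y, radii)
  d_near <- nearest_cross_distance(self$x, self$y, other$x, other$y)
  n <- nrow(self)
  score <- numeric(n)
  undefined <- logical(n)
  r2 <- radii^2
  for (i in seq_len(n)) {
    if (n_self[i, length(radii)] == 0L) { undefined[i] <- TRUE; next }
    g_self <- (n_self[i, ] / r2) / (n_self[i, length(radii)] / r_max^2)
    denom_other <- n_other[i, length(radii)]
    if (denom_other == 0L) { undefined[i] <- TRUE; next }
    g_other <- (n_other[i, ] / r2) / (denom_other / r_max^2)
    rho <- suppressWarnings(stats::cor(g_self, g_other, method = "spearman"))
    if (is.na(rho)) { undefined[i] <- TRUE; next }
    score[i] <- rho * exp(-d_near[i] / r_max)
  }
  list(score = score, undefined = undefined, d_near = d_near)
}

#' Degree-of-colocalization scores for two channels
#'
#' For every point, neighbour counts of both channels are taken on a linear
#' radius ladder up to `r_max`; each count series is converted to a density
#' gradient `N(r)/r^2` normalized by its value at `r_max`, and the DoC
#' score is the Spearman rank correlation of the two gradients multiplied
#' by `exp(-d/r_max)` with `d` the distance to the nearest point of the
#' other channel.  Scores lie in [-1, 1]: 1 means perfect colocalization,
#' -1 segregation.  Points with no same-channel (or no other-channel)
#' neighbour within `r_max` get score 0 and are counted as undefined.
#'
#' @param chA,chB [localization_table()]s, both non-empty.
#' @param r_max largest radius in nm (default 500).
#' @param n_radii number of radii on the ladder (>= 4, default 10).
#' @param threshold colocalization threshold on the score (default 0.4).
#' @return a `doc_result`: list with `scoreA`, `scoreB` (per-point),
#'   `undefinedA`, `undefinedB`, `pct_colocalizedA/B` (percent of points at
#'   or above the threshold), `threshold`, `radii`.
#' @export
doc_scores <- function(chA, chB, r_max = 500, n_radii = 10,
                       threshold = 0.4) {
  if (nrow(chA) == 0L || nrow(chB) == 0L) {
    stop_param("both channels must be non-empty")
  }
  check_number(r_max, "r_max", lower = .Machine$double.eps)
  check_number(n_radii, "n_radii", lower = 4)
  radii <- seq(r_max / n_radii, r_max, length.out = n_radii)
  a <- doc_scores_one_channel(chA, chB, radii)
  b <- doc_scores_one_channel(chB, chA, radii)
  structure(list(
    scoreA = a$score, scoreB = b$score,
    undefinedA = a$undefined, undefinedB = b$undefined,
    pct_colocalizedA = 100 * mean(a$score >= threshold),
    pct_colocalizedB = 100 * mean(b$score >= threshold),
    threshold = threshold, radii = radii), class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf(paste0("<doc_result> %d + %d points, threshold %.2f: ",
                     "%.1f%% / %.1f%% colocalized\n"),
              length(x$scoreA), length(x$scoreB), x$threshold,
              x$pct_colocalizedA, x$pct_colocalizedB))
  invisible(x)
}

summarise_coloc_channel <- function(score, threshold, clusters,
                                    min_coloc_points) {
  labels <- clusters$labels
  ids <- clusters$clusters$id
  flag <- vapply(ids, function(id) {
    sum(score[labels == id] >= threshold) >= min_coloc_points
  }, logical(1))
  per <- clusters$clusters
  mean_or_na <- function(v) if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  list(
    cluster_flags = stats::setNames(flag, ids),
    n_coloc = sum(flag), n_noncoloc = sum(!flag),
    frac_coloc = if (length(flag)) mean(flag) else NA_real_,
    mean_area_coloc = mean_or_na(per$area_nm2[flag]),
    mean_area_noncoloc = mean_or_na(per$area_nm2[!flag]),
    mean_density_coloc = mean_or_na(per$density[flag]),
    mean_density_noncoloc = mean_or_na(per$density[!flag]))
}

#' Colocalized-cluster summary for two clustered channels
#'
#' A cluster is colocalized when it contains at least `min_coloc_points`
#' members whose DoC score reaches the threshold.  Counts, mean areas and
#' densities are reported for colocalized vs non-colocalized clusters per
#' channel, together with their ratios (NA when a group is empty).
#'
#' @param doc a [doc_scores()] result.
#' @param clustersA,clustersB `cluster_result`s for the two scored tables.
#' @param min_coloc_points member threshold (default 5, the minimum cluster
#'   size).
#' @return a `coloc_summary` list with elements `channelA`, `channelB`
#'   (per-channel summaries) and `area_ratioA/B`, `density_ratioA/B`
#'   (colocalized over non-colocalized).
#' @export
coloc_cluster_summary <- function(doc, clustersA, clustersB,
                                  min_coloc_points = 5L) {
  if (length(doc$scoreA) != length(clustersA$labels) ||
      length(doc$scoreB) != length(clustersB$labels)) {
    stop_param("cluster labels do not align with the scored tables")
  }
  a <- summarise_coloc_channel(doc$scoreA, doc$threshold, clustersA,
                               min_coloc_points)
  b <- summarise_coloc_channel(doc$scoreB, doc$threshold, clustersB,
                               min_coloc_points)
  ratio <- function(x, y) if (is.na(x) || is.na(y) || y == 0) NA_real_ else x / y
  structure(list(
    channelA = a, channelB = b,
    area_ratioA = ratio(a$mean_area_coloc, a$mean_area_noncoloc),
    area_ratioB = ratio(b$mean_area_coloc, b$mean_area_noncoloc),
    density_ratioA = ratio(a$mean_density_coloc, a$mean_density_noncoloc),
    density_ratioB = ratio(b$mean_density_coloc, b$mean_density_noncoloc)),
    class = "coloc_summary")
}
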