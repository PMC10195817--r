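# Independent brute-force oracles.  Each re-derives its quantity from the
# definition with the simplest possible code, deliberately sharing no
# internals with the package implementation.

# Naive O(n^2) DBSCAN: cores from full distance matrix, clusters as
# connected components of the core graph (numbered by smallest core row
# index), border points joining the lowest-labelled cluster with a core
# neighbour.
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbh <- d <= eps
  core <- rowSums(nbh) >= min_pts      # diagonal TRUE counts the point itself
  labels <- rep(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cluster <- cluster + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == -1L &
                      apply(nbh[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (length(grow) == 0L) break
      comp <- c(comp, grow)
      labels[comp] <- cluster          # provisional, keeps loop simple
    }
    labels[comp] <- cluster
  }
  for (i in which(!core)) {
    cl <- labels[nbh[i, ] & core]
    cl <- cl[cl > 0L]
    if (length(cl)) labels[i] <- min(cl)
  }
  labels
}

# Double-loop Ripley K -> L(r) - r with the same guard-band rule, written
# directly from the definition.
oracle_ripley <- function(x, y, roi, radii) {
  n <- length(x)
  area <- smquant::polygon_area(roi)
  rmax <- max(radii)
  bd <- smquant:::dist_to_boundary(x, y, roi)
  centres <- which(bd >= rmax)
  k <- vapply(radii, function(r) {
    total <- 0
    for (i in centres) {
      for (j in seq_len(n)) {
        if (j == i) next
        if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) total <- total + 1
      }
    }
    area * total / (length(centres) * (n - 1))
  }, numeric(1))
  sqrt(k / pi) - radii
}

# Double-loop time-averaged MSD.
oracle_msd <- function(track, max_lag_fraction = 0.5) {
  n <- nrow(track)
  kmax <- max(1L, floor(max_lag_fraction * n))
  vapply(seq_len(kmax), function(k) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (track$x[i + k] - track$x[i])^2 +
        (track$y[i + k] - track$y[i])^2 + (track$z[i + k] - track$z[i])^2
    }
    acc / (n - k)
  }, numeric(1))
}

# Direct per-point DoC score for channel A against channel B.
oracle_doc_scores <- function(ax, ay, bx, by, r_max, n_radii) {
  radii <- seq(r_max / n_radii, r_max, length.out = n_radii)
  n <- length(ax)
  score <- numeric(n)
  for (i in seq_len(n)) {
    da <- sqrt((ax - ax[i])^2 + (ay - ay[i])^2)
    da <- da[-i]
    db <- sqrt((bx - ax[i])^2 + (by - ay[i])^2)
    na_r <- vapply(radii, function(r) sum(da <= r), numeric(1))
    nb_r <- vapply(radii, function(r) sum(db <= r), numeric(1))
    if (na_r[n_radii] == 0 || nb_r[n_radii] == 0) { score[i] <- 0; next }
    ga <- (na_r / radii^2) / (na_r[n_radii] / r_max^2)
    gb <- (nb_r / radii^2) / (nb_r[n_radii] / r_max^2)
    rho <- suppressWarnings(stats::cor(ga, gb, method = "spearman"))
    score[i] <- if (is.na(rho)) 0 else rho * exp(-min(db) / r_max)
  }
  score
}

# Exhaustive-rotation caliper widths of a pixel mask (0.1 degree steps).
oracle_bounds <- function(mask, pixel_size) {
  rr <- row(mask)[mask]; cc <- col(mask)[mask]
  pts <- rbind(cbind(cc - 1, rr - 1), cbind(cc, rr - 1),
               cbind(cc - 1, rr), cbind(cc, rr)) * pixel_size
  ang <- seq(0, pi, by = 0.1 * pi / 180)
  widths <- vapply(ang, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  c(min(widths), max(widths))
}

# Straight-line threshold mask (no smoothing), for comparing the masking
# rule itself.
oracle_mask <- function(heights, k_sigma) {
  heights > mean(heights) + k_sigma * stats::sd(as.vector(heights))
}
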