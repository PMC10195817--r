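# Synthetic SMLM point patterns: complete spatial randomness and two-channel
# Thomas-type cluster scenes with a controllable colocalized fraction.
# Every generator is a pure function of its parameters and seed.

# Uniform sampling inside a polygon by rejection from the bounding box.
runif_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], poly)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Simulate a completely spatially random (CSR) localization table
#'
#' Places `n` molecules i.i.d. uniform over the ROI and jitters each by an
#' isotropic Gaussian localization error of SD `precision` — the null model
#' against which the linearised Ripley's K statistic is read.
#'
#' @param roi two-column polygon matrix (nm), non-degenerate.
#' @param n number of molecules (>= 0).
#' @param precision localization precision in nm (> 0), stored per point.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return a [localization_table()] with the ROI attached.
#' @export
simulate_csr <- function(roi, n, precision = 20, seed = NULL) {
  roi <- as.matrix(roi)
  if (polygon_area(roi) <= 0) stop_param("roi polygon has zero area")
  check_number(n, "n", lower = 0)
  check_number(precision, "precision", lower = .Machine$double.eps)
  with_seed_or_current(seed, {
    p <- runif_in_polygon(n, roi)
    if (n > 0) {
      p[, 1] <- p[, 1] + stats::rnorm(n, 0, precision)
      p[, 2] <- p[, 2] + stats::rnorm(n, 0, precision)
    }
    localization_table(p[, 1], p[, 2], precision = precision, roi = roi)
  })
}

#' Parameters of a two-channel clustered scene
#'
#' Describes a Thomas-type cluster process: cluster centres uniform in the
#' ROI, member counts Poisson, members scattered isotropically (Gaussian,
#' SD `cluster_sd`) about their centre, plus a uniform background fraction.
#' A `coloc_fraction` of channel B's centres is copied from channel A, which
#' is what makes cluster-level colocalization controllable.
#'
#' @param roi polygon matrix (nm).
#' @param n_clusters number of cluster centres per channel.
#' @param molecules_per_cluster mean Poisson member count per cluster.
#' @param cluster_sd Gaussian scatter of members about the centre (nm, > 0).
#' @param background_fraction fraction of each channel's molecules placed
#'   uniformly over the ROI, in [0, 1].
#' @param precision_mean,precision_sd per-point localization precision is
#'   drawn Normal(mean, sd) truncated > 0 (nm).
#' @param coloc_fraction fraction of channel-B cluster centres shared with
#'   channel A, in [0, 1].
#' @param seed integer seed.
#' @return a `cluster_scene_params` list.
#' @export
cluster_scene_params <- function(roi = square_roi(5000),
                                 n_clusters = 20,
                                 molecules_per_cluster = 44,
                                 cluster_sd = 25,
                                 background_fraction = 0.2,
                                 precision_mean = 20,
                                 precision_sd = 4,
                                 coloc_fraction = 0,
                                 seed = NULL) {
  check_number(n_clusters, "n_clusters", lower = 0)
  check_number(molecules_per_cluster, "molecules_per_cluster", lower = 0)
  check_number(cluster_sd, "cluster_sd", lower = .Machine$double.eps)
  check_number(background_fraction, "background_fraction", 0, 1)
  check_number(coloc_fraction, "coloc_fraction", 0, 1)
  check_number(precision_mean, "precision_mean", lower = .Machine$double.eps)
  check_number(precision_sd, "precision_sd", lower = 0)
  structure(list(roi = as.matrix(roi), n_clusters = n_clusters,
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_sd = cluster_sd,
                 background_fraction = background_fraction,
                 precision_mean = precision_mean, precision_sd = precision_sd,
                 coloc_fraction = coloc_fraction, seed = seed),
            class = "cluster_scene_params")
}

rprec <- function(n, mean, sd) {
  p <- stats::rnorm(n, mean, sd)
  while (any(p <= 0)) p[p <= 0] <- stats::rnorm(sum(p <= 0), mean, sd)
  p
}

simulate_one_channel <- function(centres, params, shared_flag) {
  n_cl <- nrow(centres)
  counts <- stats::rpois(n_cl, params$molecules_per_cluster)
  cl_id <- rep(seq_len(n_cl), counts)
  n_clustered <- sum(counts)
  x <- centres[cl_id, 1] + stats::rnorm(n_clustered, 0, params$cluster_sd)
  y <- centres[cl_id, 2] + stats::rnorm(n_clustered, 0, params$cluster_sd)
  bf <- params$background_fraction
  n_bg <- if (bf >= 1) 0L else round(n_clustered * bf / (1 - bf))
  bg <- runif_in_polygon(n_bg, params$roi)
  x <- c(x, bg[, 1]); y <- c(y, bg[, 2])
  cl_id <- c(cl_id, rep(0L, n_bg))           # 0 = background
  prec <- rprec(length(x), params$precision_mean, params$precision_sd)
  locs <- localization_table(x, y, prec, roi = params$roi)
  truth <- data.frame(cluster = cl_id,
                      shared = ifelse(cl_id > 0, shared_flag[pmax(cl_id, 1L)],
                                      FALSE))
  list(locs = locs, truth = truth,
       centres = data.frame(x = centres[, 1], y = centres[, 2],
                            shared = shared_flag))
}

#' Simulate a two-channel clustered scene with known colocalization
#'
#' Channel A follows the Thomas process described by `params`; channel B is
#' built the same way with `coloc_fraction` of its cluster centres copied
#' from channel A.  Ground-truth per-point cluster labels (0 = background)
#' and per-cluster shared-centre flags are returned alongside, so downstream
#' cluster and colocalization analysis can be scored without re-deriving
#' them.
#'
#' @param params a [cluster_scene_params()].
#' @return list with `channelA`, `channelB` (localization tables), `truthA`,
#'   `truthB` (per-point cluster id and shared flag), and `centresA`,
#'   `centresB`.
#' @export
simulate_clustered_channels <- function(params) {
  stopifnot(inherits(params, "cluster_scene_params"))
  with_seed_or_current(params$seed, {
    n_cl <- params$n_clusters
    centresA <- runif_in_polygon(n_cl, params$roi)
    n_shared <- round(params$coloc_fraction * n_cl)
    shared_idx <- if (n_shared > 0) sample.int(n_cl, n_shared) else integer(0)
    centresB <- runif_in_polygon(n_cl, params$roi)
    if (n_shared > 0) centresB[seq_len(n_shared), ] <- centresA[shared_idx, ]
    sharedA <- seq_len(n_cl) %in% shared_idx
    sharedB <- seq_len(n_cl) <= n_shared
    a <- simulate_one_channel(centresA, params, sharedA)
    b <- simulate_one_channel(centresB, params, sharedB)
    list(channelA = a$locs, channelB = b$locs,
         truthA = a$truth, truthB = b$truth,
         centresA = a$centres, centresB = b$centres)
  })
}
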