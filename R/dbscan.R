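# DBSCAN clustering of localization tables.  The neighbourhood radius
# (epsilon) defaults to the mean localization precision of the table, the
# convention used when cluster maps are built from STORM data; the minimum
# cluster size is 5 molecules.

#' DBSCAN clustering parameters
#'
#' @param eps neighbourhood radius in nm (> 0); `NULL` means "use the mean
#'   of the table's precision column" (falling back to 20 nm, the typical
#'   far-red dye localization precision, when the column is absent).
#' @param min_pts minimum neighbours (including the point itself) for a
#'   core point, and the minimum cluster size (default 5).
#' @param smoothing density-map smoothing setting carried for provenance
#'   with exported cluster maps; the hull-based cluster areas computed here
#'   do not use it (default 7).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(eps = NULL, min_pts = 5L, smoothing = 7L) {
  if (!is.null(eps)) check_number(eps, "eps", lower = .Machine$double.eps)
  check_number(min_pts, "min_pts", lower = 2)
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 smoothing = as.integer(smoothing)),
            class = "cluster_params")
}

# Neighbour lists within eps (including self), chunked O(n^2).
neighbour_lists <- function(x, y, eps) {
  n <- length(x)
  out <- vector("list", n)
  chunk <- 512L
  eps2 <- eps^2
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[idx], x, `-`)^2 + outer(y[idx], y, `-`)^2
    for (k in seq_along(idx)) out[[idx[k]]] <- which(d2[k, ] <= eps2)
  }
  out
}

#' DBSCAN cluster map of a localization table
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts`
#' neighbours within `eps` (counting itself); clusters are the connected
#' components of core points together with their border points; all other
#' points are noise (label -1).  Labels are deterministic: clusters are
#' numbered by the row index of their first member, and a border point
#' reachable from several clusters joins the one with the lower label.
#'
#' @param locs a [localization_table()]; an empty table gives an empty
#'   result.
#' @param params a [cluster_params()].
#' @return a `cluster_result`: list with `labels` (per-point integer, -1 =
#'   noise), `params` (with the resolved eps), and the per-cluster metrics
#'   and summary of [cluster_metrics()].
#' @export
cluster_dbscan <- function(locs, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  eps <- params$eps %||%
    (if (nrow(locs) > 0 && "precision" %in% names(locs)) mean(locs$precision)
     else 20)
  params$eps <- eps
  n <- nrow(locs)
  if (n == 0L) {
    res <- structure(list(labels = integer(0), params = params),
                     class = "cluster_result")
    met <- cluster_metrics(res, locs)
    res$clusters <- met$clusters; res$summary <- met$summary
    return(res)
  }
  nb <- neighbour_lists(locs$x, locs$y, eps)
  core <- lengths(nb) >= params$min_pts
  labels <- rep.int(0L, n)          # 0 = unassigned, -1 = noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- nb[[i]]
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == -1L) labels[j] <- cluster      # noise -> border
      if (labels[j] != 0L) next
      labels[j] <- cluster
      if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] <= 0L])
    }
  }
  labels[labels == 0L] <- -1L
  res <- structure(list(labels = labels, params = params),
                   class = "cluster_result")
  met <- cluster_metrics(res, locs)
  res$clusters <- met$clusters
  res$summary <- met$summary
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<cluster_result> %d points, %d clusters, ",
                     "%.1f%% clustered (eps = %.3g nm, min_pts = %d)\n"),
              length(x$labels), s$n_clusters, s$pct_clustered,
              x$params$eps, x$params$min_pts))
  invisible(x)
}
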