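# Per-cluster morphometrics and the cluster summary statistics reported for
# SMLM cluster maps: percentage of molecules in clusters, number of
# clusters, mean cluster area (nm^2) and molecules per cluster.

#' Per-cluster metrics and summary for a cluster map
#'
#' Cluster area is the convex hull of the member coordinates (nm^2) and
#' density is members/area.  Clusters whose members are collinear get area
#' 0 and are excluded from the mean-area summary; their count is reported.
#' Summary means carry the standard error across clusters.
#'
#' @param result a `cluster_result` (or any list with a `labels` integer
#'   vector aligned with `locs` rows, -1 = noise).
#' @param locs the [localization_table()] that was clustered.
#' @return list with `clusters` (data frame: `id`, `n_members`, `area_nm2`,
#'   `density`, `centroid_x`, `centroid_y`) and `summary` (list:
#'   `n_points`, `n_clusters`, `pct_clustered`, `mean_area_nm2`,
#'   `sem_area_nm2`, `mean_members`, `sem_members`, `mean_density`,
#'   `n_zero_area`).
#' @export
cluster_metrics <- function(result, locs) {
  labels <- result$labels
  if (length(labels) != nrow(locs)) {
    stop_param("labels do not align with the localization table")
  }
  ids <- sort(unique(labels[labels > 0L]))
  clusters <- data.frame(id = integer(0), n_members = integer(0),
                         area_nm2 = numeric(0), density = numeric(0),
                         centroid_x = numeric(0), centroid_y = numeric(0))
  for (id in ids) {
    sel <- labels == id
    a <- hull_area(locs$x[sel], locs$y[sel])
    clusters <- rbind(clusters, data.frame(
      id = id, n_members = sum(sel), area_nm2 = a,
      density = if (a > 0) sum(sel) / a else NA_real_,
      centroid_x = mean(locs$x[sel]), centroid_y = mean(locs$y[sel])))
  }
  n <- length(labels)
  pos_area <- clusters$area_nm2[clusters$area_nm2 > 0]
  summary <- list(
    n_points = n,
    n_clusters = length(ids),
    pct_clustered = if (n > 0) 100 * sum(labels > 0L) / n else 0,
    mean_area_nm2 = if (length(pos_area)) mean(pos_area) else NA_real_,
    sem_area_nm2 = sem(pos_area),
    mean_members = if (nrow(clusters)) mean(clusters$n_members) else NA_real_,
    sem_members = sem(clusters$n_members),
    mean_density = if (any(!is.na(clusters$density)))
      mean(clusters$density, na.rm = TRUE) else NA_real_,
    n_zero_area = sum(clusters$area_nm2 == 0))
  list(clusters = clusters, summary = summary)
}
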