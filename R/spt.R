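# Mean-squared-displacement analysis of 3D trajectories, anomalous
# diffusion fitting (MSD = 2 dims D t^alpha) and mobility classification
# with the fixed thresholds: static D < 0.1, slow 0.1 <= D <= 1, diffuse
# D > 1 um^2/s.

#' Time-averaged MSD of one track
#'
#' `MSD(k dt)` averages the squared displacement over all ordered frame
#' pairs at lag k, summing over the three axes.
#'
#' @param track data frame with columns `t`, `x`, `y`, `z` (s, µm).
#' @param max_lag_fraction largest lag as a fraction of the track length,
#'   in (0, 0.5].
#' @param min_length minimum accepted track length in frames (default 10).
#' @return an `msd_curve` data frame with `lag` (s), `msd` (µm²) and
#'   `n_pairs`.
#' @export
track_msd <- function(track, max_lag_fraction = 0.5, min_length = 10L) {
  n <- nrow(track)
  if (n < min_length) {
    stop_param("track has ", n, " frames; minimum is ", min_length)
  }
  if (max_lag_fraction <= 0 || max_lag_fraction > 0.5) {
    stop_param("max_lag_fraction must lie in (0, 0.5]")
  }
  dt <- track$t[2] - track$t[1]
  kmax <- max(1L, floor(max_lag_fraction * n))
  pos <- as.matrix(track[, c("x", "y", "z")])
  msd <- numeric(kmax); npairs <- integer(kmax)
  for (k in seq_len(kmax)) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[1:(n - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d * d))
    npairs[k] <- n - k
  }
  structure(data.frame(lag = seq_len(kmax) * dt, msd = msd,
                       n_pairs = npairs),
            class = c("msd_curve", "data.frame"))
}

#' Anomalous-diffusion fit of an MSD curve
#'
#' Least-squares fit of `log(MSD) = log(2 dims D) + alpha log(t)` over the
#' first `fit_lags` usable lags (non-positive MSD values are dropped); D
#' and alpha are back-transformed and the mobility class is attached.
#'
#' @param msd an [track_msd()] curve.
#' @param dims spatial dimensionality of the MSD (3 for 3D tracks).
#' @param fit_lags number of initial lags in the fit window (default 4).
#' @return a `diffusion_fit` list: `D` (µm²/s), `alpha`, `fit_lags` used,
#'   `r_squared`, `class` (`"static"`, `"slow"`, `"diffuse"`, or
#'   `"unclassified"` when the fit failed), `ok`.
#' @export
fit_anomalous <- function(msd, dims = 3, fit_lags = 4L) {
  if (!dims %in% c(2, 3)) stop_param("dims must be 2 or 3")
  use <- utils::head(which(msd$msd > 0), fit_lags)
  if (length(use) < 4L) {
    return(structure(list(D = NA_real_, alpha = NA_real_,
                          fit_lags = length(use), r_squared = NA_real_,
                          class = "unclassified", ok = FALSE),
                     class = "diffusion_fit"))
  }
  ly <- log(msd$msd[use])
  fit <- stats::lm(ly ~ log(msd$lag[use]))
  alpha <- unname(stats::coef(fit)[2])
  D <- exp(unname(stats::coef(fit)[1])) / (2 * dims)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  structure(list(D = D, alpha = alpha, fit_lags = length(use),
                 r_squared = r2, class = classify_mobility(D), ok = TRUE),
            class = "diffusion_fit")
}

#' Mobility class from a diffusion coefficient
#'
#' Static below 0.1 µm²/s, diffuse above 1 µm²/s, slow in between; the
#' printed inequalities are strict on the outer classes, so boundary values
#' (exactly 0.1 or 1) are assigned to "slow".
#'
#' @param D diffusion coefficient in µm²/s (finite, positive) or a
#'   `diffusion_fit`.
#' @return `"static"`, `"slow"` or `"diffuse"` (vectorised over `D`).
#' @export
classify_mobility <- function(D) {
  if (inherits(D, "diffusion_fit")) {
    if (!isTRUE(D$ok)) return("unclassified")
    D <- D$D
  }
  if (anyNA(D) || any(!is.finite(D)) || any(D <= 0)) {
    stop_param("D must be finite and positive")
  }
  ifelse(D < 0.1, "static", ifelse(D > 1, "diffuse", "slow"))
}

#' Fit every track of a track set
#'
#' Convenience pipeline: per-track time-averaged MSD and anomalous fit.
#'
#' @param tracks a [track_set()].
#' @param dims,fit_lags,max_lag_fraction passed to [track_msd()] and
#'   [fit_anomalous()].
#' @return data frame with one row per track: `track`, `D`, `alpha`,
#'   `r_squared`, `class`, `ok`.
#' @export
fit_tracks <- function(tracks, dims = 3, fit_lags = 4L,
                       max_lag_fraction = 0.5) {
  ids <- attr(tracks, "ids") %||% as.character(seq_along(tracks))
  rows <- lapply(seq_along(tracks), function(i) {
    f <- fit_anomalous(track_msd(tracks[[i]], max_lag_fraction), dims,
                       fit_lags)
    data.frame(track = ids[i], D = f$D, alpha = f$alpha,
               r_squared = f$r_squared, class = f$class, ok = f$ok)
  })
  do.call(rbind, rows)
}

#' Per-cell mobility summary
#'
#' Aggregates per-track fits to per-cell mean D, mean alpha and mobility
#' composition, plus the cohort mean and SEM across cells.  Unclassified
#' (failed) fits are excluded from the percentages.
#'
#' @param fits data frame as returned by [fit_tracks()].
#' @param cell_ids vector aligning each fit with a cell.
#' @return list with `per_cell` (data frame) and `cohort` (means and SEMs
#'   across cells).
#' @export
cell_summary <- function(fits, cell_ids) {
  if (length(cell_ids) != nrow(fits)) {
    stop_param("cell_ids must align with fits")
  }
  cells <- unique(cell_ids)
  per <- lapply(cells, function(cid) {
    f <- fits[cell_ids == cid & fits$ok, , drop = FALSE]
    if (nrow(f) == 0L) stop_param("cell ", cid, " has no classified track")
    data.frame(cell = cid, n_tracks = nrow(f),
               mean_D = mean(f$D), mean_alpha = mean(f$alpha),
               pct_static = 100 * mean(f$class == "static"),
               pct_slow = 100 * mean(f$class == "slow"),
               pct_diffuse = 100 * mean(f$class == "diffuse"))
  })
  per <- do.call(rbind, per)
  num <- c("mean_D", "mean_alpha", "pct_static", "pct_slow", "pct_diffuse")
  cohort <- stats::setNames(
    lapply(num, function(cn) c(mean = mean(per[[cn]]), sem = sem(per[[cn]]))),
    num)
  list(per_cell = per, cohort = cohort)
}
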