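# AFM height-map grain analysis: sigma-multiplier masking after light
# Gaussian smoothing, border/size/median filters, caliper bounding sizes,
# KDE modes, DNA-end binding-position preference and compaction statistics.
# Input maps are assumed flattened; a plane-subtraction helper is provided.

#' Construct an AFM height map
#'
#' @param heights numeric matrix of heights in nm (rows = y, columns = x;
#'   all finite).
#' @param pixel_size nm per pixel (> 0).
#' @return a `height_map` list.
#' @export
height_map <- function(heights, pixel_size) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop_param("heights must be finite")
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px at %g nm/px, height %g..%g nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Read a height map from a plain-text matrix or TIFF
#'
#' @param path `.tif`/`.tiff` (values taken as nm) or a whitespace-separated
#'   plain-text numeric matrix.
#' @param pixel_size nm per pixel.
#' @return a [height_map()].
#' @export
read_heightmap <- function(path, pixel_size) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  h <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path, as.is = TRUE)
  } else {
    as.matrix(utils::read.table(path))
  }
  dimnames(h) <- NULL
  height_map(h, pixel_size)
}

#' Subtract a least-squares plane from a height map
#'
#' Optional levelling helper for maps that still carry a background tilt.
#'
#' @param map a [height_map()].
#' @return the levelled `height_map`.
#' @export
subtract_plane <- function(map) {
  h <- map$heights
  rr <- row(h); cc <- col(h)
  fit <- stats::lm(as.vector(h) ~ as.vector(rr) + as.vector(cc))
  height_map(h - matrix(stats::predict(fit), nrow(h), ncol(h)),
             map$pixel_size)
}

#' Grain-detection parameters
#'
#' @param k_sigma mask threshold multiplier: pixels above
#'   `mean + k_sigma * SD` of the (smoothed) map are masked.  Published
#'   values for this type of data are 0.57 (full-length protein), 0.7
#'   (C-terminal construct) and 1.5 (selective terminal-domain masking).
#' @param min_area minimum grain area in nm² (default 50; smaller grains
#'   are removed).
#' @param border_policy `"drop"` (default) or `"keep"` for grains touching
#'   the image edge.
#' @param median_window multiples of the median grain area outside which
#'   grains are dropped, length-2 `c(low, high)`; default `c(0, Inf)`
#'   disables the rule.
#' @param smooth_sigma Gaussian pre-smoothing SD in px (default 1.5).
#' @return a `grain_params` list.
#' @export
grain_params <- function(k_sigma = 0.7, min_area = 50,
                         border_policy = c("drop", "keep"),
                         median_window = c(0, Inf), smooth_sigma = 1.5) {
  check_number(k_sigma, "k_sigma", lower = .Machine$double.eps)
  check_number(min_area, "min_area", lower = 0)
  border_policy <- match.arg(border_policy)
  structure(list(k_sigma = k_sigma, min_area = min_area,
                 border_policy = border_policy,
                 median_window = median_window,
                 smooth_sigma = smooth_sigma),
            class = "grain_params")
}

#' Detect grains by sigma-multiplier height masking
#'
#' The map is lightly smoothed (Gaussian, `smooth_sigma` px), the mask is
#' `smoothed height > mean + k_sigma * SD` (mean and SD over the full
#' smoothed map), and grains are the 4-connected components of the mask.
#' Heights are reported from the unsmoothed input.
#'
#' @param map a [height_map()].
#' @param params a [grain_params()].
#' @return a `grain_set`: list with `grains` (data frame: `id`, `n_pixels`,
#'   `area_nm2`, `max_height_nm`, `centroid_x/y` in nm, `touches_border`),
#'   `labels` (label matrix, 0 = background), `threshold`, `pixel_size`,
#'   `params`.  An empty mask yields an empty grain set.
#' @export
mask_grains <- function(map, params = grain_params()) {
  stopifnot(inherits(map, "height_map"), inherits(params, "grain_params"))
  h <- map$heights
  sm <- if (params$smooth_sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(h), sigma = params$smooth_sigma,
                             boundary = "replicate"))
  } else h
  thr <- mean(sm) + params$k_sigma * stats::sd(as.vector(sm))
  mask <- sm > thr
  labels <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                   nrow(h), ncol(h))
  ids <- seq_len(max(labels, 0L))
  ps <- map$pixel_size
  grains <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    npx <- sum(sel)
    rr <- row(labels)[sel]; cc <- col(labels)[sel]
    data.frame(id = id, n_pixels = npx, area_nm2 = npx * ps^2,
               max_height_nm = max(h[sel]),
               centroid_x = mean((cc - 0.5) * ps),
               centroid_y = mean((rr - 0.5) * ps),
               touches_border = any(rr == 1L | rr == nrow(h) |
                                      cc == 1L | cc == ncol(h)))
  })) %||% data.frame()
  if (length(ids) == 0L) {
    grains <- data.frame(id = integer(0), n_pixels = integer(0),
                         area_nm2 = numeric(0), max_height_nm = numeric(0),
                         centroid_x = numeric(0), centroid_y = numeric(0),
                         touches_border = logical(0))
  }
  structure(list(grains = grains, labels = labels, threshold = thr,
                 pixel_size = ps, params = params,
                 drop_counts = c(border = 0L, size = 0L, median = 0L)),
            class = "grain_set")
}

#' @export
print.grain_set <- function(x, ...) {
  cat(sprintf("<grain_set> %d grains (threshold %.3g nm, %g nm/px)\n",
              nrow(x$grains), x$threshold, x$pixel_size))
  if (any(x$drop_counts > 0)) {
    cat("  dropped:", paste(names(x$drop_counts), x$drop_counts,
                            sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Filter grains by border contact, size and median-area window
#'
#' Applies, in order: the border rule (grains touching the image edge are
#' dropped under `border_policy = "drop"`), the minimum-area rule
#' (`< min_area` nm² dropped), and the median window (grains outside
#' `median_window * median(area)` dropped, median taken after the first two
#' rules).  Drop counts are recorded per rule.
#'
#' @param grain_set a [mask_grains()] result.
#' @param params a [grain_params()]; defaults to the set's own.
#' @return the filtered `grain_set` with updated `drop_counts`.
#' @export
filter_grains <- function(grain_set, params = grain_set$params) {
  g <- grain_set$grains
  drop_border <- if (params$border_policy == "drop") g$touches_border
  else rep(FALSE, nrow(g))
  g1 <- g[!drop_border, , drop = FALSE]
  drop_size <- g1$area_nm2 < params$min_area
  g2 <- g1[!drop_size, , drop = FALSE]
  med <- if (nrow(g2)) stats::median(g2$area_nm2) else NA_real_
  drop_med <- if (nrow(g2)) {
    g2$area_nm2 < params$median_window[1] * med |
      g2$area_nm2 > params$median_window[2] * med
  } else logical(0)
  g3 <- g2[!drop_med, , drop = FALSE]
  labels <- grain_set$labels
  labels[!(labels %in% g3$id)] <- 0L
  out <- grain_set
  out$grains <- g3
  out$labels <- labels
  out$params <- params
  out$drop_counts <- c(border = sum(drop_border), size = sum(drop_size),
                       median = sum(drop_med))
  out
}

#' Caliper bounding sizes of a grain mask
#'
#' Minimum and maximum width of support of the grain's convex hull over all
#' orientations (rotating calipers), built from the pixel corners so a
#' w x h pixel block measures w x h pixels across.  A single-pixel grain
#' reports both bounds as one pixel.
#'
#' @param mask logical matrix (the grain's pixels), or a `grain_set` plus
#'   `id`.
#' @param pixel_size nm per pixel (taken from the grain set if given).
#' @param id grain id when `mask` is a `grain_set`.
#' @return named numeric `c(min_bound, max_bound)` in nm.
#' @export
grain_bounds <- function(mask, pixel_size = NULL, id = NULL) {
  if (inherits(mask, "grain_set")) {
    pixel_size <- mask$pixel_size
    mask <- mask$labels == id
  }
  if (!any(mask)) stop_param("grain mask is empty")
  npx <- sum(mask)
  if (npx == 1L) {
    return(c(min_bound = pixel_size, max_bound = pixel_size))
  }
  rr <- row(mask)[mask]; cc <- col(mask)[mask]
  # all four corners of each pixel, in nm
  corners <- rbind(cbind(cc - 1, rr - 1), cbind(cc, rr - 1),
                   cbind(cc - 1, rr), cbind(cc, rr)) * pixel_size
  b <- caliper_bounds(unique(corners))
  c(min_bound = b[1], max_bound = b[2])
}

#' Append bounding sizes to a grain set
#'
#' @param grain_set a `grain_set`.
#' @return the set with `min_bound_nm` and `max_bound_nm` columns added.
#' @export
add_grain_bounds <- function(grain_set) {
  g <- grain_set$grains
  if (nrow(g) == 0L) {
    g$min_bound_nm <- numeric(0); g$max_bound_nm <- numeric(0)
  } else {
    b <- t(vapply(g$id, function(id)
      grain_bounds(grain_set, id = id), numeric(2)))
    g$min_bound_nm <- b[, 1]; g$max_bound_nm <- b[, 2]
  }
  grain_set$grains <- g
  grain_set
}

#' Mode of a kernel density estimate
#'
#' Gaussian kernel with Silverman's bandwidth on a 512-point grid spanning
#' the data; the mode is the grid argmax (ties broken toward the lower
#' value) and the spread is the sample SD, the "KDE max ± SD" convention
#' used to report particle sizes.
#'
#' @param values numeric vector (>= 10 values unless constant).
#' @return named numeric `c(mode, sd)`.
#' @export
kde_mode <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_param("no values")
  if (length(unique(values)) == 1L) {
    return(c(mode = values[1], sd = 0))
  }
  if (length(values) < 10L) stop_param("at least 10 values are required")
  d <- stats::density(values, bw = "nrd0", n = 512)
  c(mode = d$x[which.max(d$y)], sd = stats::sd(values))
}

#' Binding position along a DNA contour, as % distance from the nearest end
#'
#' Projects each site onto the polyline, measures the arc length to the
#' nearer end and expresses it as a percentage of the contour length
#' (0-50%).  Sites within 25% of either end are labelled `"edge"` (the two
#' edge regions jointly cover half the molecule), the rest `"middle"`.
#' Sites farther than `capture_radius` from the polyline are unassigned
#' (NA) and counted.
#'
#' @param polyline ordered two-column matrix of contour points (nm) with
#'   positive arc length.
#' @param sites two-column matrix (or length-2 vector) of binding sites
#'   (nm).
#' @param capture_radius maximum site-to-contour distance in nm
#'   (default 15).
#' @return data frame with `percent` (0-50, NA if unassigned), `region`
#'   (`"edge"`/`"middle"`/NA), `dist_nm` (site-to-contour distance);
#'   attribute `n_unassigned`.
#' @export
dna_binding_position <- function(polyline, sites, capture_radius = 15) {
  polyline <- as.matrix(polyline)
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 2)
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total <= 0) stop_param("polyline arc length must be > 0")
  arc0 <- c(0, cumsum(seg_len))
  out <- data.frame(percent = numeric(nrow(sites)),
                    region = character(nrow(sites)),
                    dist_nm = numeric(nrow(sites)))
  for (k in seq_len(nrow(sites))) {
    px <- sites[k, 1]; py <- sites[k, 2]
    best_d <- Inf; best_s <- NA_real_
    for (e in seq_len(nrow(seg))) {
      vx <- seg[e, 1]; vy <- seg[e, 2]
      len2 <- vx^2 + vy^2
      tpar <- if (len2 == 0) 0 else
        min(1, max(0, ((px - polyline[e, 1]) * vx +
                         (py - polyline[e, 2]) * vy) / len2))
      dx <- px - (polyline[e, 1] + tpar * vx)
      dy <- py - (polyline[e, 2] + tpar * vy)
      d <- sqrt(dx^2 + dy^2)
      if (d < best_d) { best_d <- d; best_s <- arc0[e] + tpar * seg_len[e] }
    }
    if (best_d > capture_radius) {
      out$percent[k] <- NA_real_; out$region[k] <- NA_character_
    } else {
      pct <- 100 * min(best_s, total - best_s) / total
      out$percent[k] <- pct
      out$region[k] <- if (pct < 25) "edge" else "middle"
    }
    out$dist_nm[k] <- best_d
  }
  attr(out, "n_unassigned") <- sum(is.na(out$percent))
  out
}

#' Compare bounding-size distributions with and without a binding partner
#'
#' Normalized histograms over a shared binning, their overlap area, group
#' medians, a Wilcoxon rank-sum shift test, and the direction of the median
#' shift (negative = compaction, i.e. the "with" sample is smaller).
#'
#' @param bounds_without,bounds_with maximum bounding sizes (nm), each with
#'   at least 10 values.
#' @param n_bins number of shared histogram bins (default 30).
#' @return a `compaction_stats` list: `breaks`, `prop_without`,
#'   `prop_with`, `overlap` (0-1), `median_without`, `median_with`,
#'   `median_shift`, `shift_sign`, `wilcox_p`.
#' @export
compaction_stats <- function(bounds_without, bounds_with, n_bins = 30) {
  if (length(bounds_without) < 10L || length(bounds_with) < 10L) {
    stop_param("both samples need at least 10 values")
  }
  rng <- range(c(bounds_without, bounds_with))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p_wo <- hist_props(bounds_without, breaks)
  p_wi <- hist_props(bounds_with, breaks)
  shift <- stats::median(bounds_with) - stats::median(bounds_without)
  w <- stats::wilcox.test(bounds_with, bounds_without, exact = FALSE)
  structure(list(breaks = breaks, prop_without = p_wo, prop_with = p_wi,
                 overlap = sum(pmin(p_wo, p_wi)),
                 median_without = stats::median(bounds_without),
                 median_with = stats::median(bounds_with),
                 median_shift = shift, shift_sign = sign(shift),
                 wilcox_p = w$p.value),
            class = "compaction_stats")
}

hist_props <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L) / length(x)
}
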