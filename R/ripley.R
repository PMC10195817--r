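# Linearised Ripley's K statistic for polygonal ROIs with guard-band edge
# handling: points within max(radii) of the boundary are excluded as centres
# but kept as neighbours, which preserves the zero reference under CSR.

#' Linearised Ripley's K function, L(r) - r
#'
#' Estimates `K(r) = A * sum_i n_i(r) / (n_c * (n - 1))`, where the sum runs
#' over guard-band centres (points at least `max(radii)` from the ROI
#' boundary), `n_i(r)` counts other points within `r`, `A` is the ROI area,
#' `n_c` the number of centres and `n` the total point count.  The
#' variance-stabilised linearisation `L(r) - r = sqrt(K(r)/pi) - r` is 0
#' under complete spatial randomness and positive under clustering.
#'
#' @param locs a [localization_table()].
#' @param roi polygon (nm); defaults to the table's attached ROI.
#' @param radii strictly increasing radii in nm; the largest must not
#'   exceed `max_radius_fraction` of the ROI's minimum caliper width.
#' @param max_radius_fraction guard ceiling for `max(radii)` (default 0.25).
#' @return a `ripley_curve`: data frame with `r` and `l_minus_r`, plus
#'   attributes `n_points`, `n_centres`, `roi_area`.
#' @export
ripley_l_minus_r <- function(locs, roi = attr(locs, "roi"),
                             radii = seq(20, 500, by = 20),
                             max_radius_fraction = 0.25) {
  if (is.null(roi)) stop_param("an ROI polygon is required")
  roi <- as.matrix(roi)
  if (any(diff(radii) <= 0) || any(radii <= 0)) {
    stop_param("radii must be positive and strictly increasing")
  }
  inside <- point_in_polygon(locs$x, locs$y, roi)
  x <- locs$x[inside]; y <- locs$y[inside]
  n <- length(x)
  if (n < 2L) stop_param("at least 2 points inside the ROI are required")
  width <- caliper_bounds(roi)[1]
  rmax <- max(radii)
  if (rmax > max_radius_fraction * width) {
    stop_param("max radius ", rmax, " nm exceeds ", max_radius_fraction,
               " of the ROI's minimum caliper width (limit ",
               signif(max_radius_fraction * width, 4), " nm)")
  }
  centres <- which(dist_to_boundary(x, y, roi) >= rmax)
  if (length(centres) == 0L) {
    stop_param("guard band of ", rmax, " nm leaves no centre points")
  }
  counts <- count_neighbours(x, y, centres, radii)
  area <- polygon_area(roi)
  k <- area * counts / (length(centres) * (n - 1))
  structure(data.frame(r = radii, l_minus_r = sqrt(k / pi) - radii),
            n_points = n, n_centres = length(centres), roi_area = area,
            class = c("ripley_curve", "data.frame"))
}

# Total neighbour counts (excluding self) within each radius, summed over
# centre points; chunked so the distance block stays small.
count_neighbours <- function(x, y, centres, radii) {
  nr <- length(radii)
  counts <- numeric(nr)
  chunk <- 512L
  r2 <- radii^2                            # compare squared distances
  for (s in seq(1, length(centres), by = chunk)) {
    idx <- centres[s:min(s + chunk - 1L, length(centres))]
    d2 <- outer(x[idx], x, `-`)^2 + outer(y[idx], y, `-`)^2
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self-pairs
    # bins = i  <=>  r2[i] < d2 <= r2[i+1]; so #(d <= radii[j]) is the
    # cumulative count of bins 0 .. j-1
    bins <- findInterval(d2, r2, left.open = TRUE)
    tab <- tabulate(bins + 1L, nbins = nr + 1L)
    counts <- counts + cumsum(tab)[seq_len(nr)]
  }
  counts
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf("<ripley_curve> %d radii (%g-%g nm), %d points (%d centres)\n",
              nrow(x), min(x$r), max(x$r), attr(x, "n_points"),
              attr(x, "n_centres")))
  invisible(x)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r, x$l_minus_r, type = "l", xlab = "r (nm)",
                 ylab = "L(r) - r (nm)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
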