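# Synthetic AFM scenes: a worm-like-chain DNA contour rendered as a ridge on
# a height map, optionally decorated with globular protein blobs at known
# contour fractions.  Ground truth (chain polyline, blob positions) is
# returned so binding-position and compaction analyses can be scored.

# Discrete worm-like chain in the plane: unit steps of length `step` with
# Gaussian tangent-angle increments of variance step / persistence_length.
wlc_chain <- function(n_steps, step, persistence_length, start, theta0) {
  dtheta <- stats::rnorm(n_steps, 0, sqrt(step / persistence_length))
  theta <- theta0 + cumsum(dtheta)
  x <- start[1] + cumsum(c(0, step * cos(theta)))
  y <- start[2] + cumsum(c(0, step * sin(theta)))
  cbind(x = x, y = y)
}

#' Simulate an AFM height map containing a DNA contour and protein blobs
#'
#' A discrete worm-like chain of total contour length `dna_length` is drawn
#' (tangent-angle Gaussian steps, variance step/persistence_length), rendered
#' as a ridge of height `dna_height` and ~2 px width, and Gaussian blobs of
#' amplitude `blob_height` are stamped at the stated fractional positions
#' along the contour.  Heights combine by maximum, so with zero noise and no
#' blobs the map's maximum equals `dna_height` exactly.  Background Gaussian
#' noise of SD `noise_sd` is added last.
#'
#' If the chain leaves the usable area the draw is retried
#' (`max_retries` times) before failing with a suggestion to enlarge the
#' map.
#'
#' @param map_size map side length in pixels.
#' @param pixel_size nm per pixel.
#' @param dna_length DNA contour length in nm (> 0).
#' @param persistence_length worm-like-chain persistence length in nm (> 0);
#'   large values give a nearly straight chain.
#' @param dna_height ridge height in nm.
#' @param blob_positions fractional positions along the contour (0-1) at
#'   which protein blobs are placed; may be empty.
#' @param blob_height,blob_sd blob amplitude (nm) and Gaussian SD (nm).
#' @param noise_sd background noise SD in nm.
#' @param max_retries re-draws allowed before giving up.
#' @param seed integer seed.
#' @return list with `map` (a [height_map()]) and `truth` (chain polyline in
#'   nm, blob xy positions, blob contour fractions, contour length).
#' @export
simulate_afm_scene <- function(map_size = 256, pixel_size = 2,
                               dna_length = 115.26, persistence_length = 50,
                               dna_height = 2, blob_positions = numeric(0),
                               blob_height = 4, blob_sd = 6,
                               noise_sd = 0.1, max_retries = 50,
                               seed = NULL) {
  check_number(dna_length, "dna_length", lower = .Machine$double.eps)
  check_number(persistence_length, "persistence_length",
               lower = .Machine$double.eps)
  check_number(blob_positions, "blob_positions", 0, 1, allow_zero_len = TRUE)
  with_seed_or_current(seed, {
    step <- pixel_size / 2          # dense sampling relative to the grid
    n_steps <- max(2L, ceiling(dna_length / step))
    step <- dna_length / n_steps    # exact contour length
    extent <- map_size * pixel_size
    margin <- 4 * pixel_size
    chain <- NULL
    for (try in seq_len(max_retries)) {
      start <- c(stats::runif(1, extent * 0.25, extent * 0.75),
                 stats::runif(1, extent * 0.25, extent * 0.75))
      cand <- wlc_chain(n_steps, step, persistence_length, start,
                        stats::runif(1, 0, 2 * pi))
      if (all(cand > margin & cand < extent - margin)) { chain <- cand; break }
    }
    if (is.null(chain)) {
      stop_param("worm-like chain escaped the map after ", max_retries,
                 " retries; increase map_size or shorten dna_length")
    }
    heights <- matrix(0, map_size, map_size)
    ridge_sd <- 1 * pixel_size      # ~2 px full width
    heights <- stamp_gaussians(heights, pixel_size, chain,
                               rep(dna_height, nrow(chain)), ridge_sd)
    arc <- c(0, cumsum(sqrt(rowSums(diff(chain)^2))))
    blob_xy <- NULL
    if (length(blob_positions) > 0) {
      target <- blob_positions * arc[length(arc)]
      idx <- vapply(target, function(s) which.min(abs(arc - s)), integer(1))
      blob_xy <- chain[idx, , drop = FALSE]
      heights <- stamp_gaussians(heights, pixel_size, blob_xy,
                                 rep(blob_height, nrow(blob_xy)), blob_sd)
    }
    if (noise_sd > 0) {
      heights <- heights + matrix(stats::rnorm(map_size^2, 0, noise_sd),
                                  map_size, map_size)
    }
    list(map = height_map(heights, pixel_size),
         truth = list(polyline = chain, blob_xy = blob_xy,
                      blob_fractions = blob_positions,
                      contour_length = arc[length(arc)]))
  })
}

# Max-combine Gaussian bumps of SD `sd` (nm) and the given peak amplitudes
# at points (nm) onto the height matrix.  Row index maps to y, column to x,
# pixel centres at (i - 0.5) * pixel_size.
stamp_gaussians <- function(heights, pixel_size, pts, amps, sd) {
  n <- nrow(heights)
  rad <- ceiling(4 * sd / pixel_size)
  ax <- (seq_len(n) - 0.5) * pixel_size
  for (k in seq_len(nrow(pts))) {
    cx <- pts[k, 1]; cy <- pts[k, 2]
    ci <- round(cy / pixel_size + 0.5); cj <- round(cx / pixel_size + 0.5)
    ii <- max(1, ci - rad):min(n, ci + rad)
    jj <- max(1, cj - rad):min(n, cj + rad)
    d2 <- outer((ax[ii] - cy)^2, (ax[jj] - cx)^2, `+`)
    bump <- amps[k] * exp(-d2 / (2 * sd^2))
    heights[ii, jj] <- pmax(heights[ii, jj], bump)
  }
  heights
}

#' Simulate a height map containing one rod-shaped particle
#'
#' Renders a capsule (a segment dilated by half the width) of hard height
#' `height` at a given orientation, centred in the map, plus background
#' Gaussian noise — the synthetic stand-in for an elongated protein
#' particle with known bounding sizes (`width` across, `length` tip to
#' tip).
#'
#' @param length,width rod length and width in nm (length >= width).
#' @param height rod height in nm.
#' @param map_size map side in pixels.
#' @param pixel_size nm per pixel.
#' @param angle orientation in radians (NULL = drawn uniformly).
#' @param noise_sd background noise SD in nm.
#' @param seed integer seed.
#' @return list with `map` (a [height_map()]) and `truth`
#'   (`min_bound`, `max_bound`, `angle`).
#' @export
simulate_rod_map <- function(length = 20, width = 13, height = 2,
                             map_size = 64, pixel_size = 1, angle = NULL,
                             noise_sd = 0.05, seed = NULL) {
  if (width > length) stop_param("width must not exceed length")
  check_number(height, "height", lower = .Machine$double.eps)
  with_seed_or_current(seed, {
    ang <- angle %||% stats::runif(1, 0, pi)
    ctr <- map_size * pixel_size / 2
    seg <- (length - width) / 2
    p1 <- ctr + seg * c(cos(ang), sin(ang))
    p2 <- ctr - seg * c(cos(ang), sin(ang))
    gx <- (seq_len(map_size) - 0.5) * pixel_size
    xm <- matrix(gx, map_size, map_size)
    ym <- matrix(gx, map_size, map_size, byrow = TRUE)
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    l2 <- max(vx^2 + vy^2, .Machine$double.eps)
    tt <- pmin(1, pmax(0, ((xm - p1[1]) * vx + (ym - p1[2]) * vy) / l2))
    dd2 <- (xm - (p1[1] + tt * vx))^2 + (ym - (p1[2] + tt * vy))^2
    h <- ifelse(dd2 <= (width / 2)^2, height, 0)
    if (noise_sd > 0) h <- h + stats::rnorm(map_size^2, 0, noise_sd)
    list(map = height_map(h, pixel_size),
         truth = list(min_bound = width, max_bound = length, angle = ang))
  })
}
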