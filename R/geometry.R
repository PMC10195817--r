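# Planar geometry used by the ROI, cluster and AFM modules.
# Polygons are two-column matrices (x, y) in nm; closure is implicit.

#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix of vertices (nm); the polygon is closed
#'   implicitly.
#' @return area in nm^2 (always non-negative).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Points exactly on an edge or vertex count as inside, so the test is a
#' deterministic total function.
#'
#' @param x,y point coordinates (nm).
#' @param poly two-column vertex matrix (nm).
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (e in seq_len(nv)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # boundary check: collinear and within the segment bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_seg <- abs(cross) < 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Minimum distance from points to the polygon boundary (segments).
dist_to_boundary <- function(x, y, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  dmin <- rep(Inf, length(x))
  for (e in seq_len(nv)) {
    vx <- qx[e] - px[e]; vy <- qy[e] - py[e]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - px[e]) * vx + (y - py[e]) * vy) / len2))
    dx <- x - (px[e] + t * vx); dy <- y - (py[e] + t * vy)
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

# Axis-aligned square polygon helper (side in nm, lower-left at origin).
#' Square region of interest
#'
#' Convenience constructor for a square ROI polygon.
#'
#' @param side side length (nm).
#' @param origin lower-left corner, length-2 numeric (nm).
#' @return two-column vertex matrix.
#' @export
square_roi <- function(side, origin = c(0, 0)) {
  check_number(side, "side", lower = .Machine$double.eps)
  matrix(c(origin[1], origin[2],
           origin[1] + side, origin[2],
           origin[1] + side, origin[2] + side,
           origin[1], origin[2] + side),
         ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

# Convex hull area of a point set; 0 when degenerate (collinear or < 3 pts).
hull_area <- function(x, y) {
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)
  polygon_area(cbind(x[h], y[h]))
}

# Caliper (width-of-support) bounds of a convex point set.
# Returns c(min, max) widths over all orientations: the minimum width comes
# from rotating calipers over hull edges; the maximum width of support of a
# convex body equals its diameter.
caliper_bounds <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1L) return(c(0, 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  # diameter
  dmax <- 0
  for (i in seq_len(m)) {
    d <- sqrt((hp[, 1] - hp[i, 1])^2 + (hp[, 2] - hp[i, 2])^2)
    dmax <- max(dmax, d)
  }
  if (m < 3L) return(c(0, dmax))  # collinear set: zero width
  wmin <- Inf
  nxt <- c(seq_len(m)[-1], 1L)
  for (i in seq_len(m)) {
    ex <- hp[nxt[i], 1] - hp[i, 1]; ey <- hp[nxt[i], 2] - hp[i, 2]
    elen <- sqrt(ex * ex + ey * ey)
    if (elen == 0) next
    # distance of all vertices from the edge's supporting line
    dist <- abs((hp[, 1] - hp[i, 1]) * ey - (hp[, 2] - hp[i, 2]) * ex) / elen
    wmin <- min(wmin, max(dist))
  }
  c(wmin, dmax)
}
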