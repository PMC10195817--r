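# Localization tables: the point sets exported by SMLM reconstruction
# software (one channel each), in nm, with per-point localization precision.

#' Construct a localization table
#'
#' A localization table holds one SMLM channel's molecule positions in nm
#' together with the per-point localization precision and optional frame,
#' z and channel annotations.  An optional polygonal region of interest
#' (ROI, nm) can be attached.
#'
#' @param x,y coordinates in nm.
#' @param precision per-point localization precision in nm (> 0). A scalar
#'   is recycled.
#' @param z optional axial coordinate in nm.
#' @param frame optional integer acquisition frame per point.
#' @param channel optional small-integer channel label.
#' @param roi optional two-column polygon matrix (nm).
#' @return a `localization_table` (a data frame with columns `x`, `y`,
#'   `precision` and any optional columns, plus a `roi` attribute).
#' @export
localization_table <- function(x, y, precision,
                               z = NULL, frame = NULL, channel = NULL,
                               roi = NULL) {
  n <- length(x)
  if (length(y) != n) stop_param("x and y must have equal length")
  if (n > 0) {
    check_number(x, "x"); check_number(y, "y")
    if (length(precision) == 1L) precision <- rep(precision, n)
    check_number(precision, "precision", lower = .Machine$double.eps)
  } else {
    precision <- numeric(0)
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   precision = as.numeric(precision))
  if (!is.null(z)) { check_number(z, "z", allow_zero_len = TRUE); df$z <- as.numeric(z) }
  if (!is.null(frame)) df$frame <- as.integer(frame)
  if (!is.null(channel)) df$channel <- as.integer(channel)
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (ncol(roi) != 2L || nrow(roi) < 3L) stop_param("roi must be a polygon matrix")
  }
  structure(df, roi = roi, class = c("localization_table", "data.frame"))
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d localizations", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", mean precision %.1f nm", mean(x$precision)))
  }
  if (!is.null(attr(x, "roi"))) {
    cat(sprintf(", ROI area %.3g nm^2", polygon_area(attr(x, "roi"))))
  }
  cat("\n")
  invisible(x)
}

#' Subset a localization table to the points inside its ROI
#'
#' Boundary points count as inside (even-odd rule).
#'
#' @param locs a [localization_table()].
#' @param roi polygon to use; defaults to the table's `roi` attribute.
#' @return the subset as a `localization_table` (same ROI attribute).
#' @export
points_in_roi <- function(locs, roi = attr(locs, "roi")) {
  if (is.null(roi)) stop_param("no ROI supplied or attached to the table")
  keep <- point_in_polygon(locs$x, locs$y, roi)
  out <- locs[keep, , drop = FALSE]
  attr(out, "roi") <- roi
  class(out) <- c("localization_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Reading

#' Column-mapping dialect for localization files
#'
#' Exporters name their columns differently; a dialect maps the file's
#' headers onto the required (`x`, `y`, `precision`) and optional (`z`,
#' `frame`, `channel`) fields, and declares the coordinate unit.  Matching
#' against file headers is case-insensitive, and each field may list several
#' candidate header names; the default registry tolerates common exporter
#' variants such as `x [nm]` or `uncertainty [nm]`.
#'
#' @param x,y,precision,z,frame,channel character vectors of candidate
#'   header names (first match wins); `z`, `frame`, `channel` may be `NULL`.
#' @param units `"nm"` or `"um"`; `"um"` coordinates (and precisions) are
#'   converted to nm on read.
#' @return a `loc_dialect` list.
#' @export
loc_dialect <- function(x = c("x", "x_nm", "x [nm]", "position x [nm]"),
                        y = c("y", "y_nm", "y [nm]", "position y [nm]"),
                        precision = c("precision", "precision_nm",
                                      "uncertainty", "uncertainty [nm]",
                                      "uncertainty_xy [nm]"),
                        z = c("z", "z_nm", "z [nm]"),
                        frame = c("frame", "frame_number"),
                        channel = c("channel", "ch"),
                        units = c("nm", "um")) {
  units <- match.arg(units)
  structure(list(x = x, y = y, precision = precision, z = z,
                 frame = frame, channel = channel, units = units),
            class = "loc_dialect")
}

match_column <- function(headers, candidates) {
  if (is.null(candidates)) return(NA_integer_)
  idx <- match(tolower(candidates), tolower(headers))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) NA_integer_ else idx[1]
}

parse_numeric_column <- function(raw, column) {
  suppressWarnings(num <- as.numeric(raw))
  bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)))
  if (length(bad) > 0L) {
    stop_format("non-numeric value in column '", column, "' at row ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  num
}

#' Read a localization table from CSV/TSV
#'
#' Rows are returned in file order; coordinates and precisions are converted
#' to nm according to the dialect's declared unit.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param dialect a [loc_dialect()].
#' @param sep optional field separator override.
#' @param roi optional polygon (nm) to attach.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, dialect = loc_dialect(), sep = NULL,
                               roi = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         colClasses = "character")
  headers <- names(raw)
  scale <- if (dialect$units == "um") 1000 else 1
  get <- function(field, mandatory) {
    j <- match_column(headers, dialect[[field]])
    if (is.na(j)) {
      if (mandatory) stop_format("missing mandatory column '", field,
                                 "' (accepted headers: ",
                                 paste(dialect[[field]], collapse = ", "), ")")
      return(NULL)
    }
    parse_numeric_column(raw[[j]], headers[j])
  }
  x <- get("x", TRUE) * scale
  y <- get("y", TRUE) * scale
  prec <- get("precision", TRUE) * scale
  z <- get("z", FALSE); if (!is.null(z)) z <- z * scale
  localization_table(x, y, prec, z = z,
                     frame = get("frame", FALSE),
                     channel = get("channel", FALSE), roi = roi)
}
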