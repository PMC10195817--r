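# 3D+t trajectory sets for single-particle-tracking analysis.
# Coordinates are micrometres, times seconds; every track is time-ordered
# with a uniform frame interval dt.

#' Construct a track set
#'
#' @param tracks list of data frames, each with columns `t`, `x`, `y`, `z`
#'   (s, µm) and rows in time order with uniform spacing `dt`.
#' @param dt frame interval in seconds.
#' @param min_length minimum track length in frames; shorter tracks are
#'   dropped and counted (default 10, the usual tracking cutoff).
#' @param ids optional track identifiers (default: list names or indices).
#' @return a `track_set`: the retained tracks with attributes `dt`,
#'   `n_dropped` and `ids`.
#' @export
track_set <- function(tracks, dt, min_length = 10L, ids = NULL) {
  check_number(dt, "dt", lower = .Machine$double.eps)
  check_number(min_length, "min_length", lower = 1)
  if (is.null(ids)) ids <- names(tracks) %||% as.character(seq_along(tracks))
  tol <- 1e-6 * dt
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    if (!all(c("t", "x", "y", "z") %in% names(tr))) {
      stop_format("track ", ids[k], " lacks t/x/y/z columns")
    }
    if (nrow(tr) >= 2L) {
      dts <- diff(tr$t)
      if (any(dts <= 0)) stop_format("track ", ids[k], " times not strictly increasing")
      if (any(abs(dts - dt) > tol)) {
        stop_format("track ", ids[k], " has non-uniform frame interval")
      }
    }
    if (!all(is.finite(as.matrix(tr[, c("x", "y", "z")])))) {
      stop_format("track ", ids[k], " has non-finite coordinates")
    }
  }
  keep <- vapply(tracks, nrow, integer(1)) >= min_length
  structure(tracks[keep],
            dt = dt, ids = ids[keep], n_dropped = sum(!keep),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  lens <- vapply(x, nrow, integer(1))
  cat(sprintf("<track_set> %d tracks (dt = %g s", length(x), attr(x, "dt")))
  if (length(x) > 0) cat(sprintf(", length %d-%d frames", min(lens), max(lens)))
  cat(sprintf("), %d dropped below minimum length\n", attr(x, "n_dropped")))
  invisible(x)
}

#' Read 3D trajectories from CSV/TSV
#'
#' Expects columns `track_id`, `x`, `y`, `z` and either `t` (seconds) or
#' `frame` (converted via `dt`).  Tracks are grouped by id and sorted by
#' time; tracks shorter than `min_length` frames are dropped and counted.
#'
#' @param path file path (separator inferred from extension).
#' @param dt frame interval in seconds; mandatory with a `frame` column,
#'   inferred from the `t` column otherwise.
#' @param min_length minimum retained track length in frames (default 10).
#' @return a [track_set()]; an empty file yields an empty set with a warning.
#' @export
read_tracks <- function(path, dt = NULL, min_length = 10L) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  if (nrow(raw) == 0L) {
    warning("empty track file: ", path)
    return(track_set(list(), dt = dt %||% 1, min_length = min_length))
  }
  need <- c("track_id", "x", "y", "z")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop_format("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if ("t" %in% names(raw)) {
    tvec <- as.numeric(raw$t)
  } else if ("frame" %in% names(raw)) {
    if (is.null(dt)) stop_format("a 'frame' column requires dt to be supplied")
    tvec <- as.numeric(raw$frame) * dt
  } else {
    stop_format("missing mandatory column(s): t or frame")
  }
  key <- paste(raw$track_id, signif(tvec, 12))
  if (anyDuplicated(key)) {
    stop_format("duplicate (track_id, t) pair at row ",
                which(duplicated(key))[1])
  }
  if (is.null(dt)) {
    dts <- unlist(tapply(tvec, raw$track_id, function(v) diff(sort(v))))
    dts <- dts[dts > 0]
    if (length(dts) == 0L) stop_format("cannot infer dt from a single-frame file")
    dt <- stats::median(dts)
  }
  ord <- order(raw$track_id, tvec)
  raw <- raw[ord, , drop = FALSE]; tvec <- tvec[ord]
  ids <- unique(as.character(raw$track_id))
  tracks <- lapply(ids, function(id) {
    sel <- as.character(raw$track_id) == id
    data.frame(t = tvec[sel], x = as.numeric(raw$x[sel]),
               y = as.numeric(raw$y[sel]), z = as.numeric(raw$z[sel]))
  })
  names(tracks) <- ids
  track_set(tracks, dt = dt, min_length = min_length, ids = ids)
}
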