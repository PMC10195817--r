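# Flat-record report writing shared by all stages.

#' Write stage results to CSV or JSON
#'
#' Results are flattened to a data frame with a deterministic column order
#' (the order of first appearance).  JSON is written at full double
#' precision so that a read back reproduces the values bit for bit.
#'
#' @param results a data frame, or a list of flat records (lists/vectors of
#'   scalars) that is row-bound into one.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = NULL) {
  format <- format %||%
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  df <- if (is.data.frame(results)) results else flatten_records(results)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(df, path, row.names = FALSE)
    } else {
      # 17 significant digits guarantee an exact double round trip
      jsonlite::write_json(df, path, digits = I(17), auto_unbox = TRUE,
                           dataframe = "rows", na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_format("cannot write report to ", path, ": ",
                               conditionMessage(ok))
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path file written by [write_report()] with `format = "json"`.
#' @return a data frame.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path)
}

flatten_records <- function(results) {
  if (length(results) == 0L) return(data.frame())
  rows <- lapply(results, function(r) {
    r <- as.list(r)
    bad <- !vapply(r, function(v) is.atomic(v) && length(v) == 1L, logical(1))
    if (any(bad)) stop_format("results are not flat records (field '",
                              names(r)[bad][1], "')")
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  })
  do.call(rbind, rows)
}
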