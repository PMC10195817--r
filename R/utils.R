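# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA` for fewer than two values.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream). Generators call this so that they are pure functions of
# their parameters and seed.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stop_param <- function(...) {
  stop(structure(class = c("smquant_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("smquant_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (allow_zero_len && length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop_param(name, " must be finite and numeric")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_param(name, " must lie in [", lower, ", ", upper, "]")
  }
  invisible(x)
}
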