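# FRAP trace normalization (double + full-scale) and single-exponential
# recovery fitting, giving the half-time and mobile fraction.

#' Construct a FRAP trace
#'
#' @param t acquisition times in seconds.
#' @param bleach bleach-ROI intensity series (arbitrary units).
#' @param reference reference-ROI (e.g. whole cell) intensity series.
#' @param background background intensity series.
#' @param bleach_index frame index of the first post-bleach sample (>= 2,
#'   so at least one pre-bleach frame exists).
#' @return a `frap_trace` list.
#' @export
frap_trace <- function(t, bleach, reference, background, bleach_index) {
  n <- length(t)
  if (length(bleach) != n || length(reference) != n ||
      length(background) != n) {
    stop_param("t, bleach, reference and background must have equal length")
  }
  check_number(bleach_index, "bleach_index", lower = 2, upper = n)
  if (!all(is.finite(c(t, bleach, reference, background)))) {
    stop_param("trace intensities and times must be finite")
  }
  structure(list(t = t, bleach = bleach, reference = reference,
                 background = background,
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d pre-bleach), t = %g..%g s\n",
              length(x$t), x$bleach_index - 1L, min(x$t), max(x$t)))
  invisible(x)
}

#' Double + full-scale normalization of a FRAP trace
#'
#' Background-subtracted double normalization
#' `I_dn(t) = (ref_pre / (ref(t) - bg(t))) * ((frap(t) - bg(t)) / frap_pre)`
#' corrects acquisition photobleaching via the reference ROI (pre-values
#' are pre-bleach means), then full-scale normalization
#' `I_fs(t) = (I_dn(t) - I_dn(t_bleach)) / (1 - I_dn(t_bleach))`
#' pins the bleach frame to 0 so the recovery plateau reads directly as the
#' mobile fraction.
#'
#' @param trace a [frap_trace()].
#' @return a `frap_normalized` list: `t`, `intensity` (I_fs),
#'   `bleach_index`, `i_dn_bleach` (the subtracted bleach-depth value).
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- seq_len(trace$bleach_index - 1L)
  ref <- trace$reference - trace$background
  if (any(ref <= 0)) {
    stop_param("reference minus background is non-positive at frame ",
               which(ref <= 0)[1])
  }
  frap <- trace$bleach - trace$background
  ref_pre <- mean(ref[pre])
  frap_pre <- mean(frap[pre])
  if (frap_pre <= 0) stop_param("pre-bleach bleach-ROI intensity is non-positive")
  i_dn <- (ref_pre / ref) * (frap / frap_pre)
  i0 <- i_dn[trace$bleach_index]
  if (1 - i0 <= 0) stop_param("bleach frame is not below the pre-bleach level")
  structure(list(t = trace$t, intensity = (i_dn - i0) / (1 - i0),
                 bleach_index = trace$bleach_index, i_dn_bleach = i0),
            class = "frap_normalized")
}

#' Single-exponential FRAP recovery fit
#'
#' Fits `I(t) = M (1 - exp(-k t))` to the post-bleach part of a normalized
#' trace (time re-zeroed at the bleach frame).  Initial guesses are robust:
#' M from the final-quartile mean and k from the time at which the curve
#' first crosses M/2 (linear interpolation).  Under the full-scale
#' convention the plateau M is the mobile fraction; it is clipped to
#' [0, 1] with a warning if the fit strays outside.
#'
#' @param norm a [normalize_frap()] result.
#' @param min_post minimum number of post-bleach samples (default 10).
#' @return a `frap_fit` list: `t_half` (s), `mobile_fraction`, `k` (1/s),
#'   `rss`, `ok`, and `init` (the starting guesses).
#' @export
fit_recovery <- function(norm, min_post = 10L) {
  stopifnot(inherits(norm, "frap_normalized"))
  post <- norm$bleach_index:length(norm$t)
  if (length(post) < min_post) {
    stop_param("need at least ", min_post, " post-bleach samples")
  }
  tt <- norm$t[post] - norm$t[norm$bleach_index]
  yy <- norm$intensity[post]
  m0 <- mean(yy[tt >= stats::quantile(tt, 0.75)])
  if (!is.finite(m0) || m0 <= 0) m0 <- max(mean(yy), 0.1)
  cross <- which(yy >= m0 / 2)[1]
  t_half0 <- if (is.na(cross) || cross <= 1L) max(tt) / 4 else {
    y1 <- yy[cross - 1L]; y2 <- yy[cross]
    t1 <- tt[cross - 1L]; t2 <- tt[cross]
    if (y2 > y1) t1 + (m0 / 2 - y1) / (y2 - y1) * (t2 - t1) else t2
  }
  t_half0 <- max(t_half0, tt[2] / 2)
  init <- c(M = m0, k = log(2) / t_half0)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ M * (1 - exp(-k * tt)),
                      start = as.list(init),
                      lower = c(M = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(t_half = NA_real_, mobile_fraction = NA_real_,
                          k = NA_real_, rss = NA_real_, ok = FALSE,
                          init = init), class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  M <- unname(cf["M"]); k <- unname(cf["k"])
  if (M > 1) {
    warning("fitted mobile fraction ", signif(M, 4), " clipped to 1")
    M <- 1
  }
  structure(list(t_half = log(2) / k, mobile_fraction = M, k = k,
                 rss = sum(stats::resid(fit)^2), ok = TRUE, init = init),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (isTRUE(x$ok)) {
    cat(sprintf("<frap_fit> t1/2 = %.3g s, mobile fraction = %.3g\n",
                x$t_half, x$mobile_fraction))
  } else {
    cat("<frap_fit> fit failed; initial guesses:",
        sprintf("M = %.3g, k = %.3g", x$init["M"], x$init["k"]), "\n")
  }
  invisible(x)
}
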