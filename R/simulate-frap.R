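# Synthetic FRAP traces under the full-scale normalized convention:
# pre-bleach plateau 1, bleach floor 0, recovery to the mobile fraction.

#' Simulate a FRAP trace
#'
#' Pre-bleach frames sit at 1; from the bleach (t = 0) the intensity follows
#' `I(t) = mobile_fraction * (1 - 2^(-t / t_half))`, i.e. a single
#' exponential whose half-time is `t_half` and whose plateau is the mobile
#' fraction (full-scale convention, bleach floor 0).  Additive Gaussian
#' noise of SD `noise_sd` is applied to the bleach-ROI series.  The trace is
#' returned in raw form (flat reference, zero background) so it exercises
#' the full [normalize_frap()] + [fit_recovery()] pipeline.
#'
#' @param t_half recovery half-time in seconds (> 0).
#' @param mobile_fraction plateau of the recovery, in [0, 1].
#' @param n_pre number of pre-bleach frames (>= 1).
#' @param duration post-bleach acquisition length in seconds.
#' @param dt frame interval in seconds (> 0).
#' @param noise_sd additive Gaussian noise SD on the normalized scale.
#' @param seed integer seed.
#' @return a [frap_trace()]; attribute `truth` stores the generating
#'   parameters.
#' @export
simulate_frap <- function(t_half, mobile_fraction, n_pre = 10,
                          duration = 100, dt = 0.5, noise_sd = 0,
                          seed = NULL) {
  check_number(t_half, "t_half", lower = .Machine$double.eps)
  check_number(mobile_fraction, "mobile_fraction", 0, 1)
  check_number(n_pre, "n_pre", lower = 1)
  check_number(dt, "dt", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed_or_current(seed, {
    t_pre <- -rev(seq_len(n_pre)) * dt
    t_post <- seq(0, duration, by = dt)
    tt <- c(t_pre, t_post)
    model <- c(rep(1, n_pre),
               mobile_fraction * (1 - 2^(-t_post / t_half)))
    bleach <- model + if (noise_sd > 0) stats::rnorm(length(tt), 0, noise_sd) else 0
    tr <- frap_trace(t = tt, bleach = bleach,
                     reference = rep(1, length(tt)),
                     background = rep(0, length(tt)),
                     bleach_index = n_pre + 1L)
    attr(tr, "truth") <- list(t_half = t_half,
                              mobile_fraction = mobile_fraction,
                              noise_sd = noise_sd)
    tr
  })
}
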