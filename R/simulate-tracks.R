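# Synthetic 3D trajectories with anomalous diffusion, MSD(t) = 6 D t^alpha.
# Two constructions are offered.  Fractional Brownian motion (default) has
# stationary increments, so the per-track TIME-averaged MSD also follows
# 6 D dt^alpha — which is what per-track MSD fitting assumes.  Scaled
# Brownian motion (independent increments with age-dependent variance)
# matches 6 D t^alpha only for the ensemble MSD from the track origin; its
# time-averaged MSD is nearly linear in lag (weak ergodicity breaking), so
# it is kept as an explicit option, not the default.

#' Mobility-mixture parameters for trajectory simulation
#'
#' @param components data frame with columns `fraction`, `D` (µm²/s, > 0)
#'   and `alpha` (0 < alpha <= 2); fractions must sum to 1.
#' @param n_tracks number of tracks.
#' @param track_length frames per track (>= 2).
#' @param dt frame interval in seconds.
#' @param loc_noise localization noise SD per coordinate (µm, >= 0).
#' @param model `"fbm"` (fractional Brownian motion, default) or `"sbm"`
#'   (scaled Brownian motion); see [simulate_tracks()].
#' @param seed integer seed.
#' @return a `mobility_mixture` list.
#' @export
mobility_mixture <- function(components, n_tracks = 200, track_length = 30,
                             dt = 0.032, loc_noise = 0,
                             model = c("fbm", "sbm"), seed = NULL) {
  model <- match.arg(model)
  components <- as.data.frame(components)
  stopifnot(all(c("fraction", "D", "alpha") %in% names(components)))
  check_number(components$fraction, "fraction", 0, 1)
  if (abs(sum(components$fraction) - 1) > 1e-8) {
    stop_param("component fractions must sum to 1")
  }
  check_number(components$D, "D", lower = .Machine$double.eps)
  if (any(components$alpha <= 0) || any(components$alpha > 2)) {
    stop_param("alpha must lie in (0, 2]")
  }
  check_number(n_tracks, "n_tracks", lower = 1)
  check_number(track_length, "track_length", lower = 2)
  check_number(dt, "dt", lower = .Machine$double.eps)
  check_number(loc_noise, "loc_noise", lower = 0)
  structure(list(components = components, n_tracks = n_tracks,
                 track_length = track_length, dt = dt,
                 loc_noise = loc_noise, model = model, seed = seed),
            class = "mobility_mixture")
}

#' Simulate a track set from a mobility mixture
#'
#' Each track is assigned a mixture component with probability equal to its
#' fraction, then generated as a Gaussian process whose 3D MSD is
#' `6 D t^alpha`.  Under `model = "fbm"` (default) the per-axis positions
#' are fractional Brownian motion with covariance
#' `D (t^alpha + s^alpha - |t - s|^alpha)`: increments are stationary, so
#' per-track time-averaged MSD curves also follow `6 D dt^alpha` and
#' per-track anomalous fits recover (D, alpha).  Under `model = "sbm"`
#' (scaled Brownian motion) increments are independent with variance
#' `2 D (t_{i+1}^alpha - t_i^alpha)`: the ensemble MSD from the origin is
#' `6 D t^alpha`, but time-averaged MSDs are nearly linear in lag.
#' Independent Gaussian localization noise of SD `loc_noise` is added to
#' every coordinate afterwards.
#'
#' @param mix a [mobility_mixture()].
#' @return a [track_set()] with attribute `truth`: a data frame of the
#'   per-track component index, D and alpha.
#' @export
simulate_tracks <- function(mix) {
  stopifnot(inherits(mix, "mobility_mixture"))
  with_seed_or_current(mix$seed, {
    comp <- mix$components
    L <- mix$track_length
    times <- (seq_len(L) - 1) * mix$dt
    assign <- sample.int(nrow(comp), mix$n_tracks, replace = TRUE,
                         prob = comp$fraction)
    # one Cholesky factor per component, reused across its tracks
    chol_by_comp <- if (mix$model == "fbm") {
      lapply(seq_len(nrow(comp)), function(cix) {
        al <- comp$alpha[cix]
        tt <- times[-1]
        cv <- comp$D[cix] *
          (outer(tt^al, tt^al, `+`) - abs(outer(tt, tt, `-`))^al)
        chol(cv + diag(1e-12 * max(cv), length(tt)))
      })
    } else NULL
    tracks <- vector("list", mix$n_tracks)
    for (i in seq_len(mix$n_tracks)) {
      D <- comp$D[assign[i]]; al <- comp$alpha[assign[i]]
      pos <- if (mix$model == "fbm") {
        ch <- chol_by_comp[[assign[i]]]
        rbind(0, crossprod(ch, matrix(stats::rnorm(3 * (L - 1L)),
                                      L - 1L, 3)))
      } else {
        incr_var <- 2 * D * diff(times^al)
        vapply(1:3, function(ax) {
          cumsum(c(0, stats::rnorm(L - 1L, 0, sqrt(incr_var))))
        }, numeric(L))
      }
      if (mix$loc_noise > 0) {
        pos <- pos + matrix(stats::rnorm(3 * L, 0, mix$loc_noise), ncol = 3)
      }
      tracks[[i]] <- data.frame(t = times, x = pos[, 1], y = pos[, 2],
                                z = pos[, 3])
    }
    names(tracks) <- as.character(seq_len(mix$n_tracks))
    ts <- track_set(tracks, dt = mix$dt, min_length = 2L)
    attr(ts, "truth") <- data.frame(track = seq_len(mix$n_tracks),
                                    component = assign,
                                    D = comp$D[assign],
                                    alpha = comp$alpha[assign])
    ts
  })
}
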