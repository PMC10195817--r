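# Synthetic-data generators: determinism, parameter validation, and the
# statistical structure each generator promises.

test_that("generators are pure functions of parameters and seed", {
  roi <- square_roi(2000)
  a1 <- simulate_csr(roi, 500, 20, seed = 5)
  a2 <- simulate_csr(roi, 500, 20, seed = 5)
  expect_identical(a1$x, a2$x)

  p <- cluster_scene_params(roi = roi, n_clusters = 5, seed = 9)
  expect_identical(simulate_clustered_channels(p)$channelB$x,
                   simulate_clustered_channels(p)$channelB$x)

  mix <- mobility_mixture(data.frame(fraction = 1, D = 0.3, alpha = 1),
                          n_tracks = 5, track_length = 12, seed = 2)
  expect_identical(simulate_tracks(mix)[[3]]$z, simulate_tracks(mix)[[3]]$z)

  expect_identical(simulate_frap(5, 0.5, noise_sd = 0.05, seed = 4)$bleach,
                   simulate_frap(5, 0.5, noise_sd = 0.05, seed = 4)$bleach)
})

test_that("CSR intensity is uniform across quadrants (binomial oracle)", {
  side <- 5000
  n <- 5000
  locs <- simulate_csr(square_roi(side), n, precision = 1e-6, seed = 31)
  for (qx in 0:1) for (qy in 0:1) {
    inq <- sum(locs$x >= qx * side / 2 & locs$x < (qx + 1) * side / 2 &
                 locs$y >= qy * side / 2 & locs$y < (qy + 1) * side / 2)
    expect_lt(abs(inq - n / 4), 3 * sqrt(n * 0.25 * 0.75))
  }
  expect_equal(nrow(simulate_csr(square_roi(side), 0, 20, seed = 1)), 0L)
  expect_error(simulate_csr(cbind(c(0, 1, 2), c(0, 0, 0)), 5, 20),
               "zero area")
})

test_that("clustered channels share centres exactly at coloc_fraction 1", {
  p <- cluster_scene_params(n_clusters = 8, background_fraction = 0,
                            coloc_fraction = 1, seed = 17)
  sc <- simulate_clustered_channels(p)
  expect_setequal(round(sc$centresB$x, 9), round(sc$centresA$x, 9))
  expect_true(all(sc$truthA$cluster > 0))   # no background requested
  expect_error(cluster_scene_params(coloc_fraction = 1.2), "coloc_fraction")
})

test_that("disjoint-channel overlap matches a Monte-Carlo CSR oracle", {
  p <- cluster_scene_params(n_clusters = 12, coloc_fraction = 0,
                            background_fraction = 0, cluster_sd = 25,
                            seed = 23)
  sc <- simulate_clustered_channels(p)
  near <- function(bx, by, cx, cy, r) {
    mean(vapply(seq_along(bx), function(i)
      any((bx[i] - cx)^2 + (by[i] - cy)^2 <= r^2), logical(1)))
  }
  obs <- near(sc$channelB$x, sc$channelB$y,
              sc$centresA$x, sc$centresA$y, p$cluster_sd)
  # oracle: fraction of CSR points within cluster_sd of 12 random centres
  mc <- withr::with_seed(99, {
    vapply(1:40, function(k) {
      pts <- smquant:::runif_in_polygon(nrow(sc$channelB), p$roi)
      cen <- smquant:::runif_in_polygon(p$n_clusters, p$roi)
      near(pts[, 1], pts[, 2], cen[, 1], cen[, 2], p$cluster_sd)
    }, numeric(1))
  })
  # B is itself clustered, so its overlap with A's centres is more variable
  # than pure CSR; require agreement within a generous Monte-Carlo band
  expect_lt(abs(obs - mean(mc)), 10 * stats::sd(mc) + 0.02)
})

test_that("track generator reproduces its target MSD law", {
  # Brownian closed form: ensemble MSD at lag k near 6 D k dt
  mixb <- mobility_mixture(data.frame(fraction = 1, D = 0.5, alpha = 1),
                           n_tracks = 300, track_length = 20, dt = 0.05,
                           seed = 41)
  ts <- simulate_tracks(mixb)
  msd1 <- rowMeans(vapply(ts, function(tr) track_msd(tr)$msd, numeric(10)))
  lags <- (1:10) * 0.05
  expect_equal(msd1 / (6 * 0.5 * lags), rep(1, 10), tolerance = 0.1)

  # anomalous case: log-log regression oracle on the ensemble MSD
  mixa <- mobility_mixture(data.frame(fraction = 1, D = 0.24, alpha = 0.7),
                           n_tracks = 200, track_length = 30, dt = 0.032,
                           seed = 43)
  tsa <- simulate_tracks(mixa)
  msda <- rowMeans(vapply(tsa, function(tr) track_msd(tr)$msd, numeric(15)))
  sl <- stats::coef(stats::lm(log(msda) ~ log((1:15) * 0.032)))[2]
  expect_equal(unname(sl), 0.7, tolerance = 0.05)

  expect_error(mobility_mixture(data.frame(fraction = 1, D = 1, alpha = 2.5)),
               "alpha")
  expect_error(mobility_mixture(data.frame(fraction = c(0.5, 0.4),
                                           D = c(1, 1), alpha = c(1, 1))),
               "sum to 1")
})

test_that("FRAP generator honours its closed form", {
  tr <- simulate_frap(t_half = 7.5, mobile_fraction = 0.65, n_pre = 10,
                      duration = 100, dt = 0.5, noise_sd = 0, seed = 1)
  post <- tr$bleach_index:length(tr$t)
  tt <- tr$t[post]
  expect_equal(tr$bleach[tr$t == 0], 0)                   # bleach floor
  expect_equal(tr$bleach[which(tt == 7.5) + tr$bleach_index - 1L],
               0.65 / 2, tolerance = 1e-12)               # I(t_half) = M/2
  expect_equal(tail(tr$bleach, 1), 0.65 * (1 - 2^(-100 / 7.5)),
               tolerance = 1e-12)
  # full recovery limit
  tr1 <- simulate_frap(1, 1, duration = 60, dt = 0.5, noise_sd = 0)
  expect_equal(tail(tr1$bleach, 1), 1, tolerance = 1e-6)
  expect_error(simulate_frap(5, 0.5, dt = 0), "dt")
})

test_that("titration generator obeys the binding limits", {
  # stoichiometric limit: kd -> 0, titrant >> partner
  tc <- simulate_titration(1e-9, design = c(1, 5, 10), fixed_partner = 0.05,
                           f_free = 2, f_bound = 7)
  expect_equal(tc$signal, rep(7, 3), tolerance = 1e-6)
  # half-saturation: titrant = kd with partner -> 0
  tc2 <- simulate_titration(0.5, design = 0.5, fixed_partner = 1e-9,
                            f_free = 0, f_bound = 1)
  expect_equal(tc2$signal, 0.5, tolerance = 1e-4)
  expect_error(simulate_titration(0.2, model = "eq2"), "requires a and b")
})

test_that("AFM scene generator renders chain, blobs and ground truth", {
  sc <- simulate_afm_scene(map_size = 128, pixel_size = 2,
                           dna_length = 115.26, persistence_length = 1e9,
                           dna_height = 2, noise_sd = 0, seed = 8)
  # straight-chain limit: end-to-end equals the contour length (~115 nm)
  ends <- sc$truth$polyline[c(1, nrow(sc$truth$polyline)), ]
  expect_equal(sqrt(sum((ends[1, ] - ends[2, ])^2)), 115.26,
               tolerance = 0.02 * 115.26)
  # noiseless, blob-free map peaks at the ridge height (heights combine by
  # maximum; the peak sits within grid quantization of the nominal value)
  expect_equal(max(sc$map$heights), 2, tolerance = 0.02)
  expect_lte(max(sc$map$heights), 2)

  # blob ground truth sits at its contour fraction
  scb <- simulate_afm_scene(map_size = 128, pixel_size = 2,
                            blob_positions = 0.10, persistence_length = 1e9,
                            noise_sd = 0, seed = 8)
  pos <- dna_binding_position(scb$truth$polyline, scb$truth$blob_xy)
  expect_equal(pos$percent, 10, tolerance = 0.5)

  # a chain that cannot fit fails with advice
  expect_error(simulate_afm_scene(map_size = 32, pixel_size = 1,
                                  dna_length = 500, seed = 1),
               "map_size")
})
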