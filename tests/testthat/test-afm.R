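# AFM grain masking, filters, bounding sizes, KDE modes, binding positions
# and compaction statistics.

flat_with_blobs <- function(nrow_px = 64, blobs = list(), noise = 0,
                            seed = 1, pixel_size = 2) {
  withr::with_seed(seed, {
    h <- matrix(rnorm(nrow_px^2, 0, max(noise, 1e-6)), nrow_px, nrow_px)
    for (b in blobs) {
      ii <- b$row + (-3:3); jj <- b$col + (-3:3)
      bump <- outer(exp(-(-3:3)^2 / 4), exp(-(-3:3)^2 / 4)) * b$height
      h[ii, jj] <- h[ii, jj] + bump
    }
    height_map(h, pixel_size)
  })
}

test_that("sigma-multiplier masking finds constructed blobs", {
  map <- flat_with_blobs(blobs = list(list(row = 20, col = 20, height = 5)),
                         noise = 0.1)
  # low sigma multipliers also catch single-pixel noise excursions; the
  # border/size filters remove them, leaving exactly the constructed blob
  gs <- filter_grains(mask_grains(map, grain_params(k_sigma = 0.7)))
  expect_equal(nrow(gs$grains), 1L)
  expect_false(gs$grains$touches_border)
  expect_gt(gs$grains$max_height_nm, 3)

  # grain count is non-increasing in k_sigma; high threshold finds nothing
  counts <- vapply(c(0.5, 1, 3, 30), function(k)
    nrow(mask_grains(map, grain_params(k_sigma = k))$grains), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[4], 0L)
})

test_that("unsmoothed masking equals the direct threshold oracle", {
  for (seed in 1:6) {
    map <- flat_with_blobs(blobs = list(list(row = 15, col = 40, height = 4),
                                        list(row = 45, col = 20, height = 6)),
                           noise = 0.2, seed = seed)
    gs <- mask_grains(map, grain_params(k_sigma = 0.8, smooth_sigma = 0))
    expect_identical(gs$labels > 0, oracle_mask(map$heights, 0.8))
  }
})

test_that("grain filters apply the border, size and median rules", {
  ps <- 2   # nm/px -> pixel area 4 nm^2
  h <- matrix(0, 40, 40)
  h[1:2, 10:13] <- 10          # touches border
  h[20:21, 20:24] <- 10        # 10 px = 40 nm^2 (< 50 nm^2 rule)
  h[30:33, 5:10] <- 10         # 24 px = 96 nm^2, survives
  map <- height_map(h, ps)
  gs <- mask_grains(map, grain_params(k_sigma = 1, smooth_sigma = 0))
  expect_equal(nrow(gs$grains), 3L)
  fg <- filter_grains(gs, grain_params(k_sigma = 1, min_area = 50))
  expect_equal(nrow(fg$grains), 1L)
  expect_equal(unname(fg$drop_counts["border"]), 1L)
  expect_equal(unname(fg$drop_counts["size"]), 1L)
  expect_equal(fg$grains$area_nm2, 96)

  # identical areas: the median window drops none
  h2 <- matrix(0, 40, 40)
  h2[5:6, 5:8] <- 10; h2[20:21, 20:23] <- 10; h2[30:31, 30:33] <- 10
  gs2 <- mask_grains(height_map(h2, 4), grain_params(k_sigma = 1,
                                                     smooth_sigma = 0))
  fg2 <- filter_grains(gs2, grain_params(k_sigma = 1, min_area = 50,
                                         median_window = c(0.5, 2)))
  expect_equal(nrow(fg2$grains), 3L)
  expect_equal(unname(fg2$drop_counts["median"]), 0L)
})

test_that("caliper bounds: rectangle, disc, single pixel, rotation", {
  # 10 x 4 px rectangle at 1 nm/px: min width 4, max = diagonal 10.77
  m <- matrix(FALSE, 20, 20); m[5:8, 3:12] <- TRUE
  b <- grain_bounds(m, pixel_size = 1)
  expect_equal(unname(b["min_bound"]), 4, tolerance = 1e-9)
  expect_equal(unname(b["max_bound"]), sqrt(10^2 + 4^2), tolerance = 1e-9)
  orc <- oracle_bounds(m, 1)
  expect_equal(unname(b), orc, tolerance = 1e-4)

  # disc of diameter d: both bounds near d
  n <- 41; ctr <- 21; r_px <- 15
  disc <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <=
    r_px^2
  bd <- grain_bounds(disc, pixel_size = 1)
  expect_equal(unname(bd["min_bound"]), 2 * r_px, tolerance = 0.1)
  expect_equal(unname(bd["max_bound"]), 2 * r_px, tolerance = 0.1)

  # single-pixel grain: both bounds are one pixel
  s <- matrix(FALSE, 5, 5); s[3, 3] <- TRUE
  expect_equal(unname(grain_bounds(s, pixel_size = 2)), c(2, 2))

  # 90-degree rotation leaves bounds unchanged
  for (seed in 1:5) {
    mr <- withr::with_seed(seed, {
      mm <- matrix(FALSE, 30, 30)
      mm[sample(8:22, 1) + 0:sample(2:6, 1), sample(8:18, 1) + 0:sample(2:9, 1)] <- TRUE
      mm
    })
    b1 <- grain_bounds(mr, 1)
    b2 <- grain_bounds(t(mr[nrow(mr):1, ]), 1)    # rotate 90 degrees
    expect_equal(b2, b1, tolerance = 1e-9)
    expect_equal(unname(b1), oracle_bounds(mr, 1), tolerance = 1e-4)
  }
})

test_that("KDE mode finds peaks and handles ties and constants", {
  x <- withr::with_seed(3, rnorm(4000, 20, 2))
  km <- kde_mode(x)
  expect_lt(abs(km["mode"] - 20), 0.5)
  expect_equal(unname(km["sd"]), stats::sd(x))

  # bimodal with a taller low component: mode goes to the taller peak
  xb <- withr::with_seed(4, c(rnorm(700, 10, 1), rnorm(300, 30, 1)))
  expect_lt(abs(kde_mode(xb)["mode"] - 10), 1)

  expect_equal(unname(kde_mode(rep(7, 3))), c(7, 0))
  expect_error(kde_mode(c(1, 2, 3)), "10 values")
})

test_that("binding positions: endpoints, midpoint, reversal symmetry", {
  line <- cbind(seq(0, 100, by = 1), 0)
  ends <- dna_binding_position(line, rbind(c(0, 0), c(50, 0), c(100, 0)))
  expect_equal(ends$percent, c(0, 50, 0))
  expect_equal(ends$region, c("edge", "middle", "edge"))

  # reversing the polyline leaves %distance unchanged
  sc <- simulate_afm_scene(map_size = 128, pixel_size = 2,
                           blob_positions = c(0.19, 0.7),
                           persistence_length = 200, noise_sd = 0, seed = 5)
  fw <- dna_binding_position(sc$truth$polyline, sc$truth$blob_xy)
  bw <- dna_binding_position(sc$truth$polyline[nrow(sc$truth$polyline):1, ],
                             sc$truth$blob_xy)
  expect_equal(bw$percent, fw$percent, tolerance = 1e-9)

  # far-away site is unassigned and counted
  far <- dna_binding_position(line, c(50, 400), capture_radius = 15)
  expect_true(is.na(far$percent))
  expect_equal(attr(far, "n_unassigned"), 1L)
})

test_that("compaction statistics detect a translation shift", {
  wo <- withr::with_seed(5, rnorm(200, 100, 15))
  st_same <- compaction_stats(wo, wo)
  expect_equal(st_same$overlap, 1)
  expect_equal(st_same$median_shift, 0)

  st_shift <- compaction_stats(wo, wo - 20)
  expect_lt(st_shift$overlap, 1)
  expect_equal(st_shift$shift_sign, -1)
  expect_equal(st_shift$median_shift, -20, tolerance = 1e-9)
  expect_lt(st_shift$wilcox_p, 0.01)
})

test_that("compacted worm-like chains shift the bound distribution down", {
  e2e <- function(pl) vapply(seq_along(pl), function(i) {
    b <- caliper_bounds(pl[[i]]); b[2]
  }, numeric(1))
  sims <- function(plen, seeds) lapply(seeds, function(s)
    simulate_afm_scene(map_size = 160, pixel_size = 2, dna_length = 115.26,
                       persistence_length = plen, noise_sd = 0,
                       seed = s)$truth$polyline)
  hits <- vapply(1:6, function(rep) {
    relaxed <- e2e(sims(150, rep * 40 + 1:12))
    compact <- e2e(sims(8, rep * 40 + 13:24))
    compaction_stats(relaxed, compact)$shift_sign == -1
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("height-map IO round-trips text and TIFF", {
  h <- matrix(seq(0, 3, length.out = 64), 8, 8)
  pt <- tempfile(fileext = ".txt")
  write.table(h, pt, row.names = FALSE, col.names = FALSE)
  back <- read_heightmap(pt, pixel_size = 2)
  expect_equal(back$heights, h, tolerance = 1e-12)
  expect_equal(back$pixel_size, 2)

  # plane subtraction levels a tilted map
  tilt <- height_map(h + outer(1:8, 1:8, function(i, j) 0.5 * i - 0.2 * j),
                     2)
  lev <- subtract_plane(tilt)
  expect_lt(abs(mean(lev$heights)), 1e-9)
})
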