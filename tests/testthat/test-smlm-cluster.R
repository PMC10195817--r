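# Ripley's K, DBSCAN and cluster metrics.

test_that("two points farther apart than r give the closed-form L(r)-r", {
  roi <- square_roi(4000)
  locs <- localization_table(c(2000, 2000), c(1800, 2200), precision = 10,
                             roi = roi)
  rc <- ripley_l_minus_r(locs, roi, radii = c(100, 200))
  # K = 0 below the pair distance (400 nm), so L(r) - r = -r
  expect_equal(rc$l_minus_r, c(-100, -200))
})

test_that("Ripley curve matches the O(n^2) oracle on clustered scenes", {
  for (seed in 1:3) {
    p <- cluster_scene_params(roi = square_roi(3000), n_clusters = 6,
                              molecules_per_cluster = 15, cluster_sd = 30,
                              background_fraction = 0.3, seed = seed)
    locs <- points_in_roi(simulate_clustered_channels(p)$channelA)
    radii <- c(25, 50, 100, 200)
    rc <- ripley_l_minus_r(locs, p$roi, radii)
    expect_equal(rc$l_minus_r,
                 oracle_ripley(locs$x, locs$y, p$roi, radii),
                 tolerance = 1e-12)
    # clustering pushes the statistic above zero near the cluster scale
    expect_gt(max(rc$l_minus_r), 0)
  }
})

test_that("Ripley guards reject oversized radii", {
  roi <- square_roi(1000)
  locs <- simulate_csr(roi, 100, 10, seed = 1)
  expect_error(ripley_l_minus_r(locs, roi, radii = c(100, 600)),
               "caliper width")
  expect_error(ripley_l_minus_r(localization_table(1, 1, 1, roi = roi), roi),
               "2 points")
})

test_that("DBSCAN honours the 5-molecule minimum cluster size", {
  # 5 mutually-within-eps points form one cluster; 4 do not
  ang <- 2 * pi * (0:4) / 5
  five <- localization_table(10 * cos(ang), 10 * sin(ang), precision = 10)
  r5 <- cluster_dbscan(five, cluster_params(eps = 25, min_pts = 5))
  expect_equal(r5$summary$n_clusters, 1L)
  expect_equal(r5$summary$pct_clustered, 100)
  four <- localization_table(10 * cos(ang[1:4]), 10 * sin(ang[1:4]),
                             precision = 10)
  r4 <- cluster_dbscan(four, cluster_params(eps = 25, min_pts = 5))
  expect_equal(r4$summary$n_clusters, 0L)
  expect_true(all(r4$labels == -1L))
})

test_that("DBSCAN equals the naive oracle on random fixtures", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(50:300, 1))
    locs <- withr::with_seed(seed, {
      # half clumped, half uniform, over a 1000 nm square
      cen <- matrix(runif(10, 0, 1000), ncol = 2)
      idx <- sample(5, n, replace = TRUE)
      localization_table(
        c(cen[idx[1:(n / 2)], 1] + rnorm(n / 2, 0, 20),
          runif(n - n / 2, 0, 1000)),
        c(cen[idx[1:(n / 2)], 2] + rnorm(n / 2, 0, 20),
          runif(n - n / 2, 0, 1000)),
        precision = 15)
    })
    eps <- withr::with_seed(seed + 100, runif(1, 15, 60))
    res <- cluster_dbscan(locs, cluster_params(eps = eps, min_pts = 5))
    expect_identical(res$labels, oracle_dbscan(locs$x, locs$y, eps, 5))
  }
})

test_that("eps defaults to the mean precision and separated clumps split", {
  eps <- 20
  clump <- function(cx) cbind(cx + c(0, 5, -5, 0, 0, 3, -3, 2, -2, 0),
                              c(0, 3, -3, 5, -5, 0, 0, 2, -2, 1))
  xy <- rbind(clump(0), clump(10 * eps))
  locs <- localization_table(xy[, 1], xy[, 2], precision = eps)
  res <- cluster_dbscan(locs)          # eps from the precision column
  expect_equal(res$params$eps, eps)
  expect_equal(res$summary$n_clusters, 2L)
  expect_identical(res$labels, oracle_dbscan(locs$x, locs$y, eps, 5))
})

test_that("degenerate inputs behave: coincident points and empty tables", {
  co <- localization_table(rep(1, 7), rep(2, 7), precision = 10)
  r <- cluster_dbscan(co, cluster_params(eps = 5, min_pts = 5))
  expect_equal(r$summary$n_clusters, 1L)
  expect_equal(r$summary$pct_clustered, 100)
  expect_equal(r$clusters$area_nm2, 0)       # collinear/coincident hull
  expect_equal(r$summary$n_zero_area, 1L)

  empty <- localization_table(numeric(0), numeric(0), numeric(0))
  re <- cluster_dbscan(empty, cluster_params(eps = 5))
  expect_equal(re$summary$n_clusters, 0L)
  expect_equal(re$summary$pct_clustered, 0)
})

test_that("hull areas are exact and summaries track the generator", {
  # 100 nm square corners plus centre: hull area 1e4 nm^2
  sq <- localization_table(c(0, 100, 100, 0, 50), c(0, 0, 100, 100, 50),
                           precision = 10)
  r <- cluster_dbscan(sq, cluster_params(eps = 150, min_pts = 5))
  expect_equal(r$clusters$area_nm2, 1e4)
  expect_equal(r$clusters$density, 5 / 1e4)

  # scene built for ~44 molecules per cluster recovers that mean
  p <- cluster_scene_params(roi = square_roi(6000), n_clusters = 12,
                            molecules_per_cluster = 44, cluster_sd = 25,
                            background_fraction = 0.05,
                            precision_mean = 20, precision_sd = 2,
                            seed = 77)
  sc <- simulate_clustered_channels(p)
  res <- cluster_dbscan(sc$channelA, cluster_params(eps = 25, min_pts = 5))
  expect_equal(res$summary$mean_members, 44,
               tolerance = 3 * 44 / sqrt(12 * 44) + 0.1)
  # all-noise labelling gives 0 %
  allnoise <- list(labels = rep(-1L, nrow(sc$channelA)))
  expect_equal(cluster_metrics(allnoise, sc$channelA)$summary$pct_clustered,
               0)
})

test_that("pct_clustered is invariant under rigid motion and monotone in eps", {
  p <- cluster_scene_params(roi = square_roi(3000), n_clusters = 8,
                            molecules_per_cluster = 20, seed = 13)
  locs <- simulate_clustered_channels(p)$channelA
  base <- cluster_dbscan(locs, cluster_params(eps = 30))
  th <- 0.7
  rot <- localization_table(
    cos(th) * locs$x - sin(th) * locs$y + 500,
    sin(th) * locs$x + cos(th) * locs$y - 200, locs$precision)
  expect_equal(cluster_dbscan(rot, cluster_params(eps = 30))$summary$pct_clustered,
               base$summary$pct_clustered)
  pcts <- vapply(c(10, 20, 30, 50, 80), function(e)
    cluster_dbscan(locs, cluster_params(eps = e))$summary$pct_clustered,
    numeric(1))
  expect_true(all(diff(pcts) >= 0))
})
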