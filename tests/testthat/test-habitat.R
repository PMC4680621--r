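make_test_seamount_bathy <- function() {
  sm <- data.frame(lon = 168, lat = -23, summit_depth = -30, radius_km = 20)
  make_bathymetry(c(165, 171, -26, -20), 0.05, -3000, sm)
}

test_that("a point on the isobath has near-zero distance to it", {
  b <- make_test_seamount_bathy()
  ring <- isobath_contours(b, 200)[[1]]
  cell_diag <- 0.05 * sqrt(2) * whaletrackr:::KM_PER_DEG
  d <- distance_to_isobath(b, ring$lon[5], ring$lat[5], 200)
  expect_lt(d, cell_diag / 2)
})

test_that("isobath distance matches the Gaussian ring geometry", {
  b <- make_test_seamount_bathy()
  r_ring <- 20 * sqrt(2 * log((-30 + 3000) / (-200 + 3000)))
  cell_km <- 0.05 * whaletrackr:::KM_PER_DEG
  for (r_q in c(2, 15, 40)) {
    # query point r_q km due north of the summit
    lat_q <- -23 + r_q / whaletrackr:::KM_PER_DEG
    d <- distance_to_isobath(b, 168, lat_q, 200)
    expect_equal(d, abs(r_q - r_ring), tolerance = cell_km)
  }
})

test_that("absent contours raise a clear error", {
  b <- make_bathymetry(c(165, 167, -24, -22), 0.1, -3000)
  expect_error(distance_to_isobath(b, 166, -23, 200), "isobath not present")
})

test_that("polyline distance agrees with geosphere's dist2Line", {
  set.seed(107)
  line <- data.frame(lon = seq(166, 168, 0.05),
                     lat = -23 + cumsum(rnorm(41, 0, 0.02)))
  for (k in 1:5) {
    p <- c(166 + runif(1, 0, 2), -23 + runif(1, -1, 1))
    mine <- whaletrackr:::min_dist_to_polyline_km(p[1], p[2],
                                                  line$lon, line$lat)
    ref <- geosphere::dist2Line(p, as.matrix(line),
                                distfun = geosphere::distHaversine)[1] / 1000
    expect_equal(mine, ref, tolerance = max(0.02, 0.01 * ref))
  }
})

test_that("habitat records carry depth and both isobath distances", {
  b <- make_test_seamount_bathy()
  loc <- data.frame(whale_id = "A", time_h = c(0, 12), mode = c("ARS", "transit"),
                    lon = c(168, 166), lat = c(-23, -25))
  rec <- habitat_records(loc, b)
  expect_named(rec, c("whale_id", "time_h", "mode", "lon", "lat",
                      "depth_m", "dist_200m_km", "dist_500m_km"),
               ignore.order = TRUE)
  expect_equal(rec$depth_m[1], -30, tolerance = 1)
  expect_equal(rec$depth_m[2], -3000, tolerance = 1)
  expect_gt(rec$dist_200m_km[2], rec$dist_200m_km[1])
})

test_that("identical mode groups give F = 0 and two groups give F = t^2", {
  rec <- data.frame(mode = rep(c("ARS", "transit"), each = 3),
                    depth_m = rep(c(-100, -200, -300), 2))
  out <- compare_modes(rec, covariates = "depth_m")
  expect_equal(out$F[1], 0)

  set.seed(109)
  rec2 <- data.frame(mode = rep(c("ARS", "transit"), each = 12),
                     depth_m = -c(rnorm(12, 600, 200), rnorm(12, 2300, 300)))
  out2 <- compare_modes(rec2, covariates = "depth_m")
  tt <- t.test(abs(depth_m) ~ mode, data = rec2, var.equal = TRUE)
  expect_equal(out2$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("uncertain-mode records are excluded and empty modes warn", {
  rec <- data.frame(mode = c("ARS", "ARS", "uncertain", "uncertain"),
                    depth_m = c(-100, -120, -5000, -6000))
  expect_warning(out <- compare_modes(rec, covariates = "depth_m"),
                 "summaries only")
  expect_false("uncertain" %in% out$mode)
  expect_true(all(is.na(out$F)))
  expect_equal(out$mean[out$mode == "ARS"], 110)
})

test_that("hand-computed one-way F matches exactly", {
  # groups {1,2,3} and {3,4,5}: SSB = 6, SSE = 4, F = 6 / (4/4) = 6
  rec <- data.frame(mode = rep(c("ARS", "transit"), each = 3),
                    dist_200m_km = c(1, 2, 3, 3, 4, 5))
  out <- compare_modes(rec, covariates = "dist_200m_km")
  expect_equal(out$F[1], 6, tolerance = 1e-12)
})

test_that("feature proximity fractions sum to one and recover a known mix", {
  sites <- data.frame(name = "S", lon = 168, lat = -23, radius_km = 50)
  near_lon <- 168 + 20 / whaletrackr:::KM_PER_DEG   # ~20 km east
  loc <- data.frame(
    whale_id = "A", time_h = seq_len(100) * 12,
    lon = c(rep(near_lon, 100)), lat = -23,
    mode = c(rep("ARS", 63), rep("transit", 9), rep("uncertain", 28)))
  out <- feature_proximity_summary(loc, sites)
  expect_equal(out$n_near, 100)
  expect_equal(out$frac_ARS, 0.63)
  expect_equal(out$frac_transit, 0.09)
  expect_equal(out$frac_uncertain, 0.28)
  expect_equal(out$frac_ARS + out$frac_transit + out$frac_uncertain, 1)

  all_ars <- transform(loc, mode = "ARS")
  out2 <- feature_proximity_summary(all_ars, sites)
  expect_equal(c(out2$frac_ARS, out2$frac_transit, out2$frac_uncertain),
               c(1, 0, 0))

  far <- transform(loc, lon = 175)
  out3 <- feature_proximity_summary(far, sites)
  expect_equal(out3$n_near, 0)
  expect_true(is.na(out3$frac_ARS))
})

test_that("sampled depth at an isobath implies small isobath distance", {
  b <- make_test_seamount_bathy()
  # walk a radial line; find a point whose sampled depth is ~ -500 m
  lat_line <- seq(-23, -22.5, 0.002)
  depths <- sample_depth(b, rep(168, length(lat_line)), lat_line)
  i <- which.min(abs(depths + 500))
  d <- distance_to_isobath(b, 168, lat_line[i], 500)
  cell_diag <- 0.05 * sqrt(2) * whaletrackr:::KM_PER_DEG
  expect_lt(d, cell_diag)
})
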