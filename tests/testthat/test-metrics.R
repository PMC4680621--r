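test_that("track distance sums great-circle legs and rejects short input", {
  loc1 <- data.frame(whale_id = "W", time_h = c(0, 12),
                     lon = c(167, 167), lat = c(-22, -22))
  expect_equal(track_distance_km(loc1), 0)
  loc3 <- data.frame(whale_id = "W", time_h = c(0, 12, 24),
                     lon = c(167, 167.5, 168), lat = rep(-22, 3))
  expect_equal(track_distance_km(loc3),
               great_circle_km(167, -22, 167.5, -22) +
                 great_circle_km(167.5, -22, 168, -22))
  expect_error(track_distance_km(loc1[1, ]), "fewer than 2")
})

test_that("a 60-day straight-line track at 4 km/h covers 5760 km", {
  cfg <- sim_config(duration_days = 60, gamma = c(1, 1), sigma_proc = 0,
                    switch_prob = c(1, 0.5), start_speed_kmh = 4, seed = 2)
  tr <- simulate_true_track(cfg, "W1")
  expect_equal(track_distance_km(tr), 5760, tolerance = 1e-4)
  expect_equal(mean_speed_kmh(tr), 4, tolerance = 1e-6)
})

test_that("speed is not estimated below 10 locations, 0 when stationary", {
  loc9 <- constant_speed_locations(8, 3)    # 9 locations
  expect_true(is.na(mean_speed_kmh(loc9)))
  expect_equal(attr(mean_speed_kmh(loc9), "reason"), "not-estimated")
  still <- data.frame(whale_id = "W", time_h = (0:11) * 12,
                      lon = rep(167, 12), lat = rep(-22, 12))
  expect_equal(mean_speed_kmh(still), 0)
})

test_that("mean speed times elapsed time equals track distance on the grid", {
  cfg <- sim_config(duration_days = 40, seed = 61)
  tr <- simulate_true_track(cfg, "W1")
  v <- mean_speed_kmh(tr)
  elapsed <- max(tr$time_h) - min(tr$time_h)
  expect_equal(v * elapsed, track_distance_km(tr), tolerance = 1e-9)
})

test_that("published per-whale speeds equal distance over elapsed time where the identity holds", {
  tab <- nc_tracking_summary()
  calc <- round_half_up(tab$min_total_distance_km /
                          (tab$tag_duration_days * 24), 1)
  idrows <- which(calc == tab$mean_speed_kmh)
  expect_gte(length(idrows), 5)
  expect_true("87761-12" %in% tab$ptt[idrows])   # 8540 km / 110 d -> 3.2
  for (i in idrows) {
    n_legs <- tab$tag_duration_days[i] * 2
    loc <- constant_speed_locations(
      n_legs, tab$min_total_distance_km[i] / (tab$tag_duration_days[i] * 24))
    expect_equal(round_half_up(mean_speed_kmh(loc), 1), tab$mean_speed_kmh[i])
  }
})

test_that("migration onset needs sustained deep water past the isobath", {
  # shelf to the west (-100 m), abyss to the east (-3000 m)
  ncol_ <- 61
  lon_axis <- seq(160, 175, length.out = ncol_)
  lat_axis <- seq(-30, -15, length.out = 31)
  depth <- matrix(rep(ifelse(lon_axis < 167, -100, -3000), 31), ncol_, 31)
  bathy <- bathymetry_grid(lon_axis, lat_axis, depth)

  shallow <- data.frame(whale_id = "W", time_h = (0:19) * 12,
                        lon = seq(161, 165, length.out = 20), lat = -22)
  expect_true(is.na(detect_migration_onset(shallow, bathy)))

  # the bilinear ramp between the -100 m node at 166.75 and the -3000 m
  # node at 167.00 crosses -1000 m at a closed-form longitude; onset is
  # the first sustained grid point past it
  crossing <- data.frame(whale_id = "W", time_h = (0:59) * 12,
                         lon = seq(163, 172, length.out = 60), lat = -22)
  onset <- detect_migration_onset(crossing, bathy)
  lon_cross <- 166.75 + 0.25 * (1000 - 100) / (3000 - 100)
  first_deep <- which(crossing$lon > lon_cross)[1]
  expect_equal(onset, crossing$time_h[first_deep])

  # a 1-step deep dip followed by shallow water does not trigger onset
  dip_lon <- c(seq(161, 165, length.out = 10), 170,
               seq(165, 161, length.out = 10))
  dip <- data.frame(whale_id = "W", time_h = (0:20) * 12,
                    lon = dip_lon, lat = -22)
  expect_true(is.na(detect_migration_onset(dip, bathy)))
})

test_that("segments spanning the onset belong to migration", {
  loc <- constant_speed_locations(10, 3)
  segs <- segment_speeds(loc, onset_time_h = 60)
  expect_equal(segs$phase, c(rep("breeding", 5), rep("migration", 5)))
  segs_none <- segment_speeds(loc, NA)
  expect_true(all(segs_none$phase == "breeding"))
})

test_that("speed summary pools segments by category and phase", {
  meta <- data.frame(whale_id = c("A", "B"), sex = c("M", "F"),
                     category = c("M", "MC"))
  segs <- rbind(segment_speeds(constant_speed_locations(6, 2, whale_id = "A"), NA),
                segment_speeds(constant_speed_locations(6, 4, whale_id = "B"), NA))
  out <- speed_summary(segs, meta)
  expect_equal(sort(out$category), c("M", "MC"))
  expect_false("migration" %in% out$phase)   # absent, not zero
  expect_equal(out$mean_kmh[out$category == "M"], 2, tolerance = 1e-4)
  expect_equal(out$mean_kmh[out$category == "MC"], 4, tolerance = 1e-4)
  # pooled mean across equal segment counts
  expect_equal(mean(segs$speed_kmh), 3, tolerance = 1e-4)
})

test_that("two-factor ANOVA matches the balanced closed form", {
  set.seed(71)
  d <- expand.grid(cat = c("M", "MC"), phase = c("breeding", "migration"),
                   rep = 1:6)
  d$y <- 2 + (d$phase == "migration") * 1.5 + (d$cat == "M") * 0.5 +
    rnorm(nrow(d), 0, 0.7)
  want <- balanced_two_way_oracle(d$y, d$cat, d$phase)
  got <- two_factor_anova(d$y, d$cat, d$phase)
  expect_equal(got$F[got$term == "category"], want$F_A, tolerance = 1e-6)
  expect_equal(got$F[got$term == "phase"], want$F_B, tolerance = 1e-6)
  expect_equal(got$F[got$term == "category:phase"], want$F_AB,
               tolerance = 1e-6)
})

test_that("all-equal speeds give F = 0 for both factors", {
  d <- expand.grid(cat = c("M", "F"), phase = c("breeding", "migration"),
                   rep = 1:4)
  got <- two_factor_anova(rep(3, nrow(d)), d$cat, d$phase)
  expect_equal(got$F[got$term == "category"], 0)
  expect_equal(got$F[got$term == "phase"], 0)
})

test_that("the two-way design reduces to one-way with a single level", {
  set.seed(73)
  y <- rnorm(20)
  cat1 <- rep("M", 20)
  phase <- rep(c("breeding", "migration"), 10)
  got <- two_factor_anova(y, cat1, phase)
  ref <- anova(lm(y ~ factor(phase)))
  expect_equal(got$F[got$term == "phase"], ref$`F value`[1], tolerance = 1e-9)
})

test_that("Newman-Keuls separates well-spaced means and respects containment", {
  set.seed(79)
  y <- c(rnorm(15, 0), rnorm(15, 5), rnorm(15, 10))
  g <- rep(c("a", "b", "c"), each = 15)
  out <- newman_keuls(y, g)
  expect_true(all(out$significant))
  # one shared mean: the widest span drives everything non-significant inside
  y2 <- rnorm(45, 0)
  out2 <- newman_keuls(y2, g)
  if (!out2$significant[out2$span == 3]) {
    expect_false(any(out2$significant))
  }
})

test_that("Newman-Keuls family-wise error under the null is near nominal", {
  set.seed(83)
  n_sim <- 400
  fwer <- mean(replicate(n_sim, {
    y <- rnorm(32)
    g <- rep(c("a", "b", "c", "d"), each = 8)
    any(newman_keuls(y, g, alpha = 0.05)$significant)
  }))
  # SNK controls FWER at alpha under the complete null; Monte-Carlo 3 SE
  expect_lt(abs(fwer - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("whale summary table carries the rounding contract", {
  expect_equal(round_half_up(c(2.25, 2.24, -2.25), 1), c(2.3, 2.2, -2.3))
  expect_equal(round_half_up(3.235, 1), 3.2)
  cfg <- sim_config(n_whales = 2, duration_days = 20, seed = 89)
  fleet <- simulate_fleet(cfg)
  locs <- do.call(rbind, lapply(fleet$tracks, function(tr) {
    data.frame(whale_id = tr$whale_id, time_h = tr$time_h, lon = tr$lon,
               lat = tr$lat, b_mean = ifelse(tr$state == 1, 1.1, 1.9),
               mode = ifelse(tr$state == 1, "transit", "ARS"))
  }))
  onsets <- setNames(rep(NA_real_, 2), fleet$meta$whale_id)
  tab <- whale_summary_table(locs, fleet$meta, onsets)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pct_ARS + tab$pct_transit + tab$pct_uncertain,
               rep(100, 2), tolerance = 0.16)
  expect_true(all(is.na(tab$migratory_speed)))
})
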