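test_that("behavioural-mode thresholds are strict, boundaries uncertain", {
  expect_equal(classify_mode(1.10), "transit")
  expect_equal(classify_mode(1.90), "ARS")
  expect_equal(classify_mode(c(1.25, 1.75)), c("uncertain", "uncertain"))
  expect_equal(classify_mode(c(1, 2)), c("transit", "ARS"))
  expect_error(classify_mode(0.9), "\\[1, 2\\]")
  expect_error(classify_mode(2.1), "\\[1, 2\\]")
})

test_that("burn-in and thinning arithmetic retains 2000 draws per chain", {
  expect_identical(n_retained_draws(mcmc_config()), 2000L)
  expect_identical(n_retained_draws(mcmc_config(8000, 4000, 5)), 800L)
  expect_error(mcmc_config(n_samples = 100, n_burn = 200))
})

test_that("with no observations the sampler returns the prior", {
  # marginally, alpha ~ Beta(1,1) (mean 1/2); gamma are iid Uniform(0,1),
  # so after the gamma1 > gamma2 relabelling their means are 2/3 and 1/3
  set.seed(99)
  raw <- whaletrackr:::.sssm_mcmc_cpp(
    numeric(0), numeric(0), integer(0), numeric(0), numeric(0), numeric(0),
    numeric(0), 5L, 60000L, 10000L, 10L,
    rep(167, 5), rep(-22, 5),
    c(0.7, 0.3, 0, 0, 0.1, 0.1, 0, 0.8, 0.8), 1.0, 167, -22, 1.0)
  rel <- whaletrackr:::relabel_draws(raw)
  expect_equal(mean(rel$params[, 8]), 0.5, tolerance = 0.08)
  expect_equal(mean(rel$params[, 9]), 0.5, tolerance = 0.08)
  expect_equal(mean(rel$params[, 1]), 2 / 3, tolerance = 0.08)
  expect_equal(mean(rel$params[, 2]), 1 / 3, tolerance = 0.08)
})

test_that("a single-state transit track is never classified as ARS", {
  # with no behavioural contrast in the data the second state is
  # unidentified (it mimics the first), so the defensible posterior
  # behaviour is transit-or-uncertain everywhere, a clear majority of
  # state draws in transit, and not a single ARS classification
  cfg <- sim_config(duration_days = 60, switch_prob = c(1, 0.5),
                    gamma = c(0.85, 0.15), seed = 41)
  tr <- simulate_true_track(cfg, "W1")
  expect_true(all(tr$state == 1))
  fx <- filter_argos(simulate_argos_fixes(tr, cfg))$fixes
  fit <- fit_sssm(fx, mcmc = mcmc_config(4000, 2000, 5, seed = 41))
  reg <- regularize(fit)
  expect_false(any(reg$mode == "ARS"))
  expect_gt(mean(fit$states == 1), 0.65)
})

test_that("near-noiseless on-grid fixes recover positions within 1 km", {
  # one exact class-3 fix at every grid time: the posterior mean must sit
  # on the truth everywhere
  cfg <- sim_config(duration_days = 40, seed = 43)
  tr <- simulate_true_track(cfg, "W1")
  fx <- data.frame(ptt = "W1", time_h = tr$time_h, lc = "3",
                   lon = tr$lon, lat = tr$lat, stringsAsFactors = FALSE)
  em <- argos_error_model(scale_km = c(`3` = 0.05, `2` = 0.5, `1` = 1.5,
                                       `0` = 4, A = 6, B = 10))
  fit <- fit_sssm(fx, mcmc = mcmc_config(4000, 2000, 5, seed = 43),
                  error_model = em)
  reg <- regularize(fit)
  truth <- whaletrackr:::interp_track(tr, reg$time_h)
  err_km <- great_circle_km(reg$lon, reg$lat, truth$lon, truth$lat)
  expect_lt(max(err_km), 1)
})

test_that("grid anchoring yields floor(span/12) + 1 regular locations", {
  cfg <- sim_config(duration_days = 10, argos_rates = 10, seed = 47)
  tr <- simulate_true_track(cfg, "W1")
  fx <- filter_argos(simulate_argos_fixes(tr, cfg))$fixes
  fit <- fit_sssm(fx, mcmc = mcmc_config(1000, 500, 5, seed = 47))
  reg <- regularize(fit)
  span <- fx$time_h[nrow(fx)] - fx$time_h[1]
  expect_equal(nrow(reg), floor(span / 12) + 1)
  expect_equal(diff(reg$time_h), rep(12, nrow(reg) - 1))
  expect_equal(reg$time_h[1], fx$time_h[1])
})

test_that("b_mean is exactly 2 when every draw is in state 2", {
  fake <- structure(list(
    params = data.frame(gamma1 = 0.8, gamma2 = 0.2),
    states = matrix(2L, 50, 4),
    pos_lon = matrix(167, 50, 4), pos_lat = matrix(-22, 50, 4),
    grid_time_h = seq(0, 36, 12), whale_id = "F1",
    rhat = c(gamma1 = 1), mcmc = mcmc_config(100, 50, 1, 1)),
    class = "sssm_fit")
  reg <- regularize(fake)
  expect_equal(reg$b_mean, rep(2, 4))
  expect_equal(reg$mode, rep("ARS", 4))
})

test_that("too-short tracks raise an insufficient-data error", {
  fx <- data.frame(ptt = "A", time_h = seq(0, 6, 1), lc = "3",
                   lon = 167 + (0:6) / 100, lat = rep(-22, 7))
  expect_error(fit_sssm(fx), "insufficient data")
  fx2 <- data.frame(ptt = "A", time_h = seq(0, 7, 1), lc = "3",
                    lon = 167 + (0:7) / 100, lat = rep(-22, 8))
  expect_error(fit_sssm(fx2), "insufficient data")
})

test_that("an interior observation gap is bridged smoothly", {
  cfg <- sim_config(duration_days = 30, argos_rates = 8, seed = 53,
                    gamma = c(0.9, 0.2), switch_prob = c(1, 0.5),
                    start_speed_kmh = 3)
  tr <- simulate_true_track(cfg, "W1")
  fx <- filter_argos(simulate_argos_fixes(tr, cfg))$fixes
  mid <- mean(range(fx$time_h))
  gap <- fx$time_h > mid - 12 & fx$time_h < mid + 12  # empty 2-step span
  fx <- fx[!gap, , drop = FALSE]
  fit <- fit_sssm(fx, mcmc = mcmc_config(2000, 1000, 5, seed = 53))
  reg <- regularize(fit)
  expect_true(all(is.finite(reg$lon)) && all(is.finite(reg$lat)))
  legs <- great_circle_km(reg$lon[-nrow(reg)], reg$lat[-nrow(reg)],
                          reg$lon[-1], reg$lat[-1])
  expect_true(all(legs < 12 * 12))  # no wild jumps across the gap
})

test_that("relabelling enforces gamma1 > gamma2 on every draw", {
  raw <- list(params = cbind(c(0.2, 0.9), c(0.7, 0.1), c(0.5, 0), c(0, 0.5),
                             c(0.1, 0.1), c(0.1, 0.1), c(0, 0),
                             c(0.6, 0.9), c(0.8, 0.7)),
              states = matrix(c(1L, 2L, 2L, 1L), 2, 2))
  rel <- whaletrackr:::relabel_draws(raw)
  expect_true(all(rel$params[, 1] > rel$params[, 2]))
  expect_equal(rel$states[1, ], c(2L, 1L))   # flipped with the swap
  expect_equal(rel$states[2, ], c(2L, 1L))   # untouched
  expect_equal(rel$params[1, 8], 0.8)        # alphas swapped too
})

test_that("draw archive round-trips through plain text", {
  cfg <- sim_config(duration_days = 10, seed = 59)
  tr <- simulate_true_track(cfg, "W1")
  fx <- filter_argos(simulate_argos_fixes(tr, cfg))$fixes
  fit <- fit_sssm(fx, mcmc = mcmc_config(500, 250, 5, seed = 59))
  dir <- tempfile()
  save_draws(fit, dir)
  expect_true(all(file.exists(file.path(
    dir, c("params.csv", "states.csv", "pos_lon.csv", "pos_lat.csv",
           "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$mcmc$n_samples, 500)
  back <- read.csv(file.path(dir, "params.csv"))
  expect_equal(nrow(back), nrow(fit$params))
})
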