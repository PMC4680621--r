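# Synthetic-data generator: ground-truthed two-state movement tracks,
# Argos-like irregular noisy fixes, whale metadata, and (in bathymetry.R) a
# seamount-bearing depth raster. The generator is first-class, tested code:
# it provides the statistical structure the analysis assumes, with known
# truth for parameter- and state-recovery checks.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

# Deterministic sub-seed derivation so per-whale streams are independent but
# fully reproducible from one master seed (kept below 2^31).
derive_seed <- function(seed, ...) {
  k <- as.numeric(seed) %% 2147483647
  for (v in c(...)) {
    for (ch in utf8ToInt(as.character(v))) {
      k <- (k * 31 + ch) %% 2147483647
    }
  }
  as.integer(k)
}

#' Simulation configuration for the two-state movement generator
#'
#' Defines a fleet of whales moving by a first-difference correlated random
#' walk that switches between two behavioural states: state 1 ("transit",
#' fast and directionally persistent) and state 2 ("ARS", area-restricted
#' search: slow, with turning dominated by process noise). Argos-like fixes
#' are then observed at irregular times with class-dependent error.
#'
#' Defaults caricature the two modes seen in humpback telemetry: strong
#' persistence in transit (`gamma = c(0.8, 0.2)`), no mean rotation
#' (`theta = c(0, 0)`; low persistence already makes state-2 headings
#' noise-dominated), process noise of 0.15 degrees per 12-h step
#' (roughly 17 km, giving transit speeds near 2-3 km/h), sticky states
#' (`switch_prob = c(0.95, 0.95)`, mean dwell 10 days), 8 fixes/day, and a
#' literature-typical Argos class mix and error scales (class 3 about
#' 0.3 km through class B about 10 km; class Z fixes are corrupted junk).
#'
#' @param n_whales number of animals in the fleet.
#' @param duration_days tag lifetime, days.
#' @param step_hours true-state step, hours (12 matches the analysis grid).
#' @param gamma length-2 persistence coefficients in \[0,1\]
#'   (index 1 = transit, 2 = ARS).
#' @param theta length-2 mean turn angles, radians.
#' @param sigma_proc process standard deviation, degrees per step.
#' @param switch_prob `c(P(stay transit), P(stay ARS))`, both in (0,1).
#' @param argos_rates mean number of fixes per day.
#' @param lc_probs probability vector over classes 3,2,1,0,A,B,Z; must sum
#'   to 1.
#' @param lc_error_scale per-class isotropic observation error scale, km.
#' @param start_lon,start_lat deployment location, degrees (default: the
#'   Southern Lagoon of New Caledonia, 167 E / 22.5 S).
#' @param start_speed_kmh optional initial speed, km/h: the first
#'   displacement is due east at this speed instead of being drawn at the
#'   initial state's marginal scale (useful for constructing deterministic
#'   straight-line tracks with `sigma_proc = 0`, `gamma = c(1, 1)`).
#' @param seed master seed; everything derived from (config, seed) is
#'   byte-identical across runs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_whales = 5, duration_days = 60, step_hours = 12,
                       gamma = c(0.8, 0.2), theta = c(0, 0),
                       sigma_proc = 0.15, switch_prob = c(0.95, 0.95),
                       argos_rates = 8,
                       lc_probs = c(0.10, 0.15, 0.20, 0.20, 0.20, 0.13, 0.02),
                       lc_error_scale = c(0.3, 0.5, 1.5, 4, 6, 10, 500),
                       start_lon = 167, start_lat = -22.5,
                       start_speed_kmh = NULL, seed = 1L) {
  if (length(gamma) != 2 || any(!is.finite(gamma)) ||
      any(gamma < 0 | gamma > 1)) {
    stop("config error in 'gamma': need two values in [0, 1]")
  }
  if (length(switch_prob) != 2 || any(!is.finite(switch_prob)) ||
      any(switch_prob <= 0 | switch_prob > 1)) {
    stop("config error in 'switch_prob': need two probabilities in (0, 1]")
  }
  if (length(theta) != 2 || any(!is.finite(theta))) {
    stop("config error in 'theta': need two finite angles")
  }
  if (length(lc_probs) != 7 || any(lc_probs < 0) ||
      abs(sum(lc_probs) - 1) > 1e-8) {
    stop("config error in 'lc_probs': need 7 non-negative values summing to 1")
  }
  if (length(lc_error_scale) != 7 || any(lc_error_scale < 0)) {
    stop("config error in 'lc_error_scale': need 7 non-negative scales (km)")
  }
  if (sigma_proc < 0) stop("config error in 'sigma_proc': must be >= 0")
  if (duration_days <= 0 || n_whales < 1 || step_hours <= 0 ||
      argos_rates <= 0) {
    stop("config error: n_whales, duration_days, step_hours, argos_rates ",
         "must be positive")
  }
  cfg <- list(n_whales = as.integer(n_whales),
              duration_days = duration_days, step_hours = step_hours,
              gamma = gamma, theta = theta, sigma_proc = sigma_proc,
              switch_prob = switch_prob, argos_rates = argos_rates,
              lc_probs = setNames(lc_probs, ARGOS_CLASSES),
              lc_error_scale = setNames(lc_error_scale, ARGOS_CLASSES),
              start_lon = start_lon, start_lat = start_lat,
              start_speed_kmh = start_speed_kmh, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a true two-state track
#'
#' Forward-simulates the switching first-difference correlated random walk:
#' a latent two-state Markov chain `b_t` (stay probabilities
#' `switch_prob`), and displacements
#' `d_t = gamma\[b_t\] R(theta\[b_t\]) d_\{t-1\} + e_t` with isotropic
#' Gaussian process noise, applied in a local tangent plane (km) and
#' converted to degrees with latitude-dependent longitude scaling.
#' Longitudes are emitted on \[0, 360) so tracks crossing the antimeridian
#' stay contiguous.
#'
#' @param config a [sim_config()].
#' @param whale_id identifier; also salts the random stream.
#' @return a `true_track`: data.frame with columns `whale_id`,
#'   `time_h` (hours since deployment, regular), `lon`, `lat`,
#'   `state` (1 = transit, 2 = ARS).
#' @export
simulate_true_track <- function(config, whale_id = "W1") {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- floor(config$duration_days * 24 / config$step_hours)
  if (n_steps < 2) stop("duration too short: need at least 2 steps")
  set.seed(derive_seed(config$seed, whale_id, "track"))

  a1 <- config$switch_prob[1]; a2 <- config$switch_prob[2]
  # stationary distribution of the 2-state chain for the initial state;
  # with two absorbing states, either start is equally defensible
  p1 <- if (a1 == 1 && a2 == 1) 0.5 else (1 - a2) / ((1 - a1) + (1 - a2))
  states <- integer(n_steps + 1)
  states[1] <- if (runif(1) < p1) 1L else 2L
  for (t in 2:(n_steps + 1)) {
    stay <- if (states[t - 1] == 1L) a1 else a2
    states[t] <- if (runif(1) < stay) states[t - 1] else 3L - states[t - 1]
  }

  sigma_km <- config$sigma_proc * KM_PER_DEG
  lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
  lon[1] <- config$start_lon; lat[1] <- config$start_lat
  # initial displacement: due east at a fixed speed if requested,
  # otherwise drawn at the first state's marginal scale
  d <- if (!is.null(config$start_speed_kmh)) {
    c(config$start_speed_kmh * config$step_hours, 0)
  } else {
    g0 <- config$gamma[states[1]]
    s0 <- if (sigma_km > 0) sigma_km / sqrt(max(1 - g0^2, 1e-6)) else 0
    rnorm(2, 0, s0)
  }
  for (t in 2:(n_steps + 1)) {
    b <- states[t]
    g <- config$gamma[b]; th <- config$theta[b]
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    d <- g * (rot %*% d) + rnorm(2, 0, sigma_km)
    lat[t] <- lat[t - 1] + d[2] / KM_PER_DEG
    lon[t] <- lon[t - 1] + d[1] / (KM_PER_DEG * cos(lat[t - 1] * pi / 180))
  }
  data.frame(whale_id = whale_id,
             time_h = (0:n_steps) * config$step_hours,
             lon = wrap_lon_360(lon), lat = lat,
             state = states, stringsAsFactors = FALSE) |>
    structure(class = c("true_track", "data.frame"))
}

# Linear interpolation of a track at arbitrary times, unwrapping longitude
# first so antimeridian crossings interpolate correctly.
interp_track <- function(track, at_h) {
  lon <- track$lon
  dl <- diff(lon)
  dl <- dl - 360 * round(dl / 360)
  lon_unwrapped <- lon[1] + c(0, cumsum(dl))
  data.frame(
    lon = wrap_lon_360(approx(track$time_h, lon_unwrapped, at_h)$y),
    lat = approx(track$time_h, track$lat, at_h)$y)
}

#' Simulate Argos-like fixes from a true track
#'
#' Fix times follow a Poisson process at `argos_rates` per day; each fix
#' draws a location class from `lc_probs` and observes the interpolated true
#' position plus isotropic Gaussian error at the class's km scale. Class-Z
#' fixes are corrupted: their error scale is the (large) Z entry of
#' `lc_error_scale`, emulating the invalid positions the preprocessing stage
#' must discard.
#'
#' @param true_track a track from [simulate_true_track()].
#' @param config the same [sim_config()].
#' @return data.frame of fixes: `ptt`, `time_h`, `lc`, `lon`, `lat`,
#'   time-sorted.
#' @export
simulate_argos_fixes <- function(true_track, config) {
  stopifnot(nrow(true_track) > 0, inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, true_track$whale_id[1], "argos"))
  span_h <- max(true_track$time_h)
  n_fix <- rpois(1, config$argos_rates * span_h / 24)
  if (n_fix == 0) {
    return(data.frame(ptt = character(0), time_h = numeric(0),
                      lc = character(0), lon = numeric(0), lat = numeric(0)))
  }
  t_fix <- sort(runif(n_fix, 0, span_h))
  pos <- interp_track(true_track, t_fix)
  lc <- sample(ARGOS_CLASSES, n_fix, replace = TRUE, prob = config$lc_probs)
  scale_km <- config$lc_error_scale[lc]
  err_lat <- rnorm(n_fix, 0, scale_km) / KM_PER_DEG
  err_lon <- rnorm(n_fix, 0, scale_km) /
    (KM_PER_DEG * cos(pos$lat * pi / 180))
  data.frame(ptt = true_track$whale_id[1], time_h = t_fix, lc = lc,
             lon = wrap_lon_360(pos$lon + err_lon),
             lat = pmax(-90, pmin(90, pos$lat + err_lat)),
             stringsAsFactors = FALSE)
}

#' Simulate per-whale metadata
#'
#' Assigns molecular sex and reproductive category — males (M), females with
#' a calf at deployment (MC), females without calves (F) — plus a social
#' group code as recorded at tagging. Category MC always implies sex F.
#'
#' @param config a [sim_config()].
#' @return data.frame: `whale_id`, `sex`, `category`, `social_group`.
#' @export
simulate_whale_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "meta"))
  ids <- sprintf("SIM%02d", seq_len(config$n_whales))
  category <- sample(c("M", "F", "MC"), config$n_whales, replace = TRUE,
                     prob = c(0.55, 0.17, 0.28))
  sex <- ifelse(category == "M", "M", "F")
  groups <- list(M = c("S", "P", "CG", "E", "2-3"),
                 F = c("S", "P", "CG"),
                 MC = c("MC", "MCE", "CG+MC"))
  social <- vapply(category, function(cat) sample(groups[[cat]], 1), "")
  data.frame(whale_id = ids, sex = sex, category = category,
             social_group = unname(social), stringsAsFactors = FALSE)
}

#' Simulate a whole tagged fleet
#'
#' Convenience wrapper producing, per whale, the true track (for evaluation
#' only), the observed Argos fixes, and shared metadata.
#'
#' @param config a [sim_config()].
#' @return list with `meta` (data.frame), `tracks` (named list of
#'   true tracks), `fixes` (one time-sorted data.frame, all whales).
#' @export
simulate_fleet <- function(config) {
  meta <- simulate_whale_meta(config)
  tracks <- lapply(meta$whale_id, function(id) simulate_true_track(config, id))
  names(tracks) <- meta$whale_id
  fixes <- do.call(rbind, lapply(tracks, simulate_argos_fixes, config = config))
  rownames(fixes) <- NULL
  list(meta = meta, tracks = tracks, fixes = fixes)
}
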