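# Bayesian switching state-space model: fit the two-state DCRW to filtered
# Argos fixes by MCMC, regularize tracks to a 12-h grid, and classify
# behavioural modes from the posterior-mean state.

#' MCMC configuration
#'
#' Defaults follow common practice for this model class: 40 000 iterations
#' per chain, the first 20 000 discarded as burn-in, and the remainder
#' thinned by 10, retaining exactly 2000 draws per chain; two chains with
#' over-dispersed starts.
#'
#' @param n_samples total iterations per chain.
#' @param n_burn burn-in iterations discarded.
#' @param thin keep one draw in every `thin`.
#' @param n_chains number of chains.
#' @param seed integer seed (chains are salted from it).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 40000, n_burn = 20000, thin = 10,
                        n_chains = 2, seed = 1L) {
  stopifnot(n_burn < n_samples, thin >= 1, n_chains >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Retained draws per chain under a configuration
#' @param config an [mcmc_config()].
#' @return integer count of post-burn-in, thinned draws per chain.
#' @export
n_retained_draws <- function(config) {
  as.integer((config$n_samples - config$n_burn) %/% config$thin)
}

#' Argos observation-error model
#'
#' Per-class t-distribution scales (km) and degrees of freedom for the
#' measurement model. Argos gives no error magnitudes with location-only
#' tags beyond the class ordering, so defaults are literature-typical
#' values (class 3 about 0.3 km through class B about 10 km, heavier tails
#' for the poorer classes); both columns are user-configurable.
#'
#' @param scale_km named numeric, per-class scale in km.
#' @param df named numeric, per-class t degrees of freedom.
#' @return data.frame with rownames 3,2,1,0,A,B.
#' @export
argos_error_model <- function(scale_km = c(`3` = 0.3, `2` = 0.5, `1` = 1.5,
                                           `0` = 4, A = 6, B = 10),
                              df = c(`3` = 10, `2` = 10, `1` = 6,
                                     `0` = 4, A = 3, B = 2)) {
  cls <- setdiff(ARGOS_CLASSES, "Z")
  stopifnot(all(cls %in% names(scale_km)), all(cls %in% names(df)),
            all(scale_km[cls] > 0), all(df[cls] > 0))
  data.frame(scale_km = scale_km[cls], df = df[cls], row.names = cls)
}

#' Classify a posterior-mean behaviour index into a mode
#'
#' The latent state is 1 (transit) or 2 (area-restricted search); the
#' posterior mean over MCMC draws lies in \[1, 2\]. Means strictly below
#' 1.25 are classified as transit, strictly above 1.75 as ARS, and anything
#' in between — including the boundary values themselves — as uncertain.
#'
#' @param b_mean numeric vector of posterior means in \[1, 2\].
#' @return character vector over `"transit"`, `"ARS"`, `"uncertain"`.
#' @export
classify_mode <- function(b_mean) {
  if (any(!is.finite(b_mean)) || any(b_mean < 1 | b_mean > 2)) {
    stop("b_mean must lie in [1, 2]")
  }
  ifelse(b_mean < 1.25, "transit", ifelse(b_mean > 1.75, "ARS", "uncertain"))
}

# Unwrap a longitude sequence to a continuous line (no 360-degree jumps).
unwrap_lon <- function(lon) {
  dl <- diff(lon)
  dl <- dl - 360 * round(dl / 360)
  lon[1] + c(0, cumsum(dl))
}

#' Fit the switching DCRW state-space model to one whale's filtered fixes
#'
#' Latent positions evolve on a regular grid (anchored at the first fix,
#' `step_hours` apart) by a first-difference correlated random walk whose
#' persistence `gamma` and rotation `theta` switch with a latent two-state
#' Markov chain; fixes are related to the bracketing grid positions by
#' linear time-interpolation with class-specific t-distributed error. The
#' native Metropolis-within-Gibbs sampler updates states by
#' forward-filtering backward-sampling, positions by adaptive single-site
#' random-walk Metropolis, `gamma`/`theta`/`Sigma` by random-walk
#' Metropolis (uniform, uniform-circular and half-Cauchy/uniform priors),
#' and the stay probabilities by conjugate Beta draws.
#'
#' Draws are relabelled so that state 1 is always the faster, straighter
#' mode (`gamma1 > gamma2`), making classification invariant to chain
#' initialization. Split R-hat is reported per movement parameter;
#' convergence is reported, not enforced.
#'
#' @param fixes time-sorted, speed-filtered fixes of a single whale
#'   (`ptt`, `time_h`, `lc`, `lon`, `lat`; no class Z).
#' @param mcmc an [mcmc_config()].
#' @param error_model an [argos_error_model()].
#' @param step_hours regular-grid spacing, hours.
#' @param prior_sigma_scale half-Cauchy scale for the process SDs, degrees.
#' @param prior_anchor_sd SD (degrees) of the vague normal prior anchoring
#'   the first grid position at the first fix and diffusing the first
#'   displacement; keeps the posterior proper and is swamped by any
#'   observation (default 1 degree, about 111 km).
#' @return an object of class `sssm_fit`: list with `params` (data.frame of
#'   retained draws, all chains, with a `chain` column), `states`
#'   (draws x grid matrix over \{1,2\}), `pos_lon`/`pos_lat` (draws x grid),
#'   `grid_time_h`, `whale_id`, `rhat`, `mcmc`.
#' @export
fit_sssm <- function(fixes, mcmc = mcmc_config(),
                     error_model = argos_error_model(),
                     step_hours = 12, prior_sigma_scale = 1,
                     prior_anchor_sd = 1) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  if (nrow(fixes) < 8) {
    stop("insufficient data: need at least 8 fixes, got ", nrow(fixes))
  }
  if (any(fixes$lc == "Z")) stop("class-Z fixes must be removed before fitting")
  if (is.unsorted(fixes$time_h)) stop("fixes must be time-sorted")

  t0 <- fixes$time_h[1]
  span <- fixes$time_h[nrow(fixes)] - t0
  n_grid <- floor(span / step_hours) + 1
  if (n_grid < 3) {
    stop("insufficient data: fixes span fewer than 2 grid intervals")
  }
  grid_h <- t0 + (seq_len(n_grid) - 1) * step_hours

  lon_u <- unwrap_lon(fixes$lon)
  # observation-to-interval mapping; trailing fixes (< one step past the
  # last grid point) extrapolate linearly on the final interval (w > 1)
  rel <- (fixes$time_h - t0) / step_hours
  idx <- pmin(floor(rel), n_grid - 2)
  w <- rel - idx
  lat_c <- cos(mean(fixes$lat) * pi / 180)
  em <- error_model[as.character(fixes$lc), ]
  tau_lat <- em$scale_km / KM_PER_DEG
  tau_lon <- em$scale_km / (KM_PER_DEG * lat_c)

  # initial positions: linear interpolation of the fixes onto the grid
  x0_lon <- approx(fixes$time_h, lon_u, grid_h, rule = 2)$y
  x0_lat <- approx(fixes$time_h, fixes$lat, grid_h, rule = 2)$y

  inits <- list(
    c(0.7, 0.3, 0, 0, 0.1, 0.1, 0, 0.8, 0.8),
    c(0.95, 0.05, 0.5, -0.5, 0.3, 0.3, 0, 0.95, 0.95),
    c(0.5, 0.5, -0.5, 0.5, 0.05, 0.05, 0, 0.6, 0.6))

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, fixes$ptt[1], "chain", ch))
    jit <- if (ch == 1) 0 else rnorm(n_grid, 0, 0.05)
    par0 <- inits[[(ch - 1) %% length(inits) + 1]]
    raw <- .sssm_mcmc_cpp(lon_u, fixes$lat, as.integer(idx), w,
                          tau_lon, tau_lat, em$df,
                          as.integer(n_grid), mcmc$n_samples, mcmc$n_burn,
                          mcmc$thin, x0_lon + jit, x0_lat + jit,
                          par0, prior_sigma_scale,
                          x0_lon[1], x0_lat[1], prior_anchor_sd)
    chains[[ch]] <- relabel_draws(raw)
  }

  par_names <- c("gamma1", "gamma2", "theta1", "theta2",
                 "sigma_lon", "sigma_lat", "rho", "alpha1", "alpha2")
  params <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    d <- as.data.frame(chains[[ch]]$params)
    names(d) <- par_names
    d$chain <- ch
    d
  }))
  states <- do.call(rbind, lapply(chains, `[[`, "states"))
  pos_lon <- do.call(rbind, lapply(chains, `[[`, "pos_lon"))
  pos_lat <- do.call(rbind, lapply(chains, `[[`, "pos_lat"))

  rhat <- if (mcmc$n_chains > 1) {
    vapply(par_names, function(pn) {
      split_rhat(vapply(chains, function(c2) {
        c2$params[, match(pn, par_names)]
      }, numeric(nrow(chains[[1]]$params))))
    }, 0)
  } else {
    setNames(rep(NA_real_, length(par_names)), par_names)
  }

  structure(list(params = params, states = states,
                 pos_lon = pos_lon, pos_lat = pos_lat,
                 grid_time_h = grid_h, whale_id = fixes$ptt[1],
                 rhat = rhat, mcmc = mcmc, n_fixes = nrow(fixes)),
            class = "sssm_fit")
}

# Enforce label identifiability: per draw, state 1 must be the high-
# persistence (faster, straighter) mode. Swapped draws flip gamma, theta,
# alpha and the state sequence together.
relabel_draws <- function(raw) {
  par <- raw$params
  sw <- par[, 1] < par[, 2]
  if (any(sw)) {
    par[sw, 1:2] <- par[sw, 2:1]
    par[sw, 3:4] <- par[sw, 4:3]
    par[sw, 8:9] <- par[sw, 9:8]
    raw$states[sw, ] <- 3L - raw$states[sw, ]
    raw$params <- par
  }
  raw
}

#' @export
print.sssm_fit <- function(x, ...) {
  cat(sprintf("Switching DCRW fit: whale %s, %d fixes, %d grid points\n",
              x$whale_id, x$n_fixes, length(x$grid_time_h)))
  cat(sprintf("  %d retained draws (%d chains); max R-hat %.3f\n",
              nrow(x$params), x$mcmc$n_chains, max(x$rhat, na.rm = TRUE)))
  pm <- colMeans(x$params[, c("gamma1", "gamma2", "alpha1", "alpha2")])
  cat(sprintf("  posterior means: gamma = (%.2f, %.2f), alpha = (%.2f, %.2f)\n",
              pm[1], pm[2], pm[3], pm[4]))
  invisible(x)
}

#' Regularized 12-h locations from a fitted model
#'
#' One location per grid time from the first to the last fix: positions are
#' posterior means over all retained draws of all chains, `b_mean` is the
#' mean of the state draws (in \[1, 2\]), and the mode label applies the
#' 1.25 / 1.75 classification rule. Warns (does not fail) if any movement
#' parameter has split R-hat above 1.1.
#'
#' @param fit an [fit_sssm()] result.
#' @return data.frame: `whale_id`, `time_h`, `lon`, `lat`, `b_mean`, `mode`.
#' @export
regularize <- function(fit) {
  stopifnot(inherits(fit, "sssm_fit"))
  if (all(is.finite(fit$rhat)) && max(fit$rhat) > 1.1) {
    warning(sprintf("whale %s: max R-hat %.2f > 1.1; inspect convergence",
                    fit$whale_id, max(fit$rhat)))
  }
  data.frame(whale_id = fit$whale_id, time_h = fit$grid_time_h,
             lon = wrap_lon_360(colMeans(fit$pos_lon)),
             lat = colMeans(fit$pos_lat),
             b_mean = colMeans(fit$states),
             mode = classify_mode(colMeans(fit$states)),
             stringsAsFactors = FALSE)
}

#' Archive retained draws as plain text
#'
#' Writes the draw matrices (parameters, states, positions) as CSV files in
#' `dir`, plus a JSON manifest embedding the MCMC configuration and seed,
#' so a fit is fully reconstructable and diffable.
#'
#' @param fit an `sssm_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_draws <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(fit$params, file.path(dir, "params.csv"), row.names = FALSE)
  write.csv(fit$states, file.path(dir, "states.csv"), row.names = FALSE)
  write.csv(fit$pos_lon, file.path(dir, "pos_lon.csv"), row.names = FALSE)
  write.csv(fit$pos_lat, file.path(dir, "pos_lat.csv"), row.names = FALSE)
  manifest <- list(whale_id = fit$whale_id, mcmc = unclass(fit$mcmc),
                   rhat = as.list(fit$rhat),
                   grid_time_h = range(fit$grid_time_h))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
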