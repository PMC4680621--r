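# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive speed-filter oracle: search deletion subsets from the largest
# retained size downwards; the first size with any feasible subset (all
# consecutive retained pairs at or below vmax) is the optimum. Independent
# of the package's dynamic-programming implementation.
oracle_speed_filter_exhaustive <- function(fx, vmax = 12) {
  n <- nrow(fx)
  sp <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- great_circle_km(fx$lon[i], fx$lat[i], fx$lon[j], fx$lat[j])
    dt <- fx$time_h[j] - fx$time_h[i]
    sp[i, j] <- ifelse(dt > 0, d / dt, ifelse(d > 0, Inf, 0))
  }
  for (k in n:1) {
    subs <- utils::combn(n, k)
    for (c1 in seq_len(ncol(subs))) {
      idx <- subs[, c1]
      if (k < 2 ||
          all(sp[cbind(idx[-k], idx[-1])] <= vmax)) {
        return(k)
      }
    }
  }
  0L
}

# Random short toy track around New Caledonia; moderate jumps so a few
# fixes violate the 12 km/h bound.
random_toy_track <- function(n) {
  data.frame(ptt = "TOY", time_h = sort(runif(n, 0, 48)), lc = "3",
             lon = 167 + cumsum(rnorm(n, 0, 0.12)),
             lat = -23 + cumsum(rnorm(n, 0, 0.12)),
             stringsAsFactors = FALSE)
}

# Regular 12-h locations moving due east at a constant speed (km/h).
constant_speed_locations <- function(n_legs, speed_kmh, lat = -22,
                                     whale_id = "W1") {
  step_km <- speed_kmh * 12
  dlon <- step_km / (great_circle_km(0, lat, 1, lat))
  data.frame(whale_id = whale_id, time_h = (0:n_legs) * 12,
             lon = 160 + (0:n_legs) * dlon, lat = lat,
             stringsAsFactors = FALSE)
}

# True state at each regularized grid time, by nearest true-track step.
truth_at_grid <- function(true_track, time_h, step_hours = 12) {
  true_track$state[pmin(nrow(true_track),
                        pmax(1, round(time_h / step_hours) + 1))]
}

# Closed-form balanced two-way ANOVA (a x b cells, r replicates): explicit
# sums-of-squares formulas, independent of lm/car.
balanced_two_way_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); N <- length(y); r <- N / (a * b)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ssa <- r * b * sum((mA - g)^2)
  ssb <- r * a * sum((mB - g)^2)
  sscell <- r * sum((mAB - g)^2)
  ssab <- sscell - ssa - ssb
  sse <- sum((y - ave(y, A, B))^2)
  dfe <- N - a * b
  list(F_A = (ssa / (a - 1)) / (sse / dfe),
       F_B = (ssb / (b - 1)) / (sse / dfe),
       F_AB = (ssab / ((a - 1) * (b - 1))) / (sse / dfe))
}
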