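# Internal helpers shared across modules.

# Mean Earth radius used everywhere distances are computed.
EARTH_RADIUS_KM <- 6371

# Degrees of latitude per km on the 6371-km sphere (and of longitude at the
# equator); longitude spacing shrinks with cos(latitude).
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.25 -> 2.3), the convention used in
#' published tracking summaries, as opposed to [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over all four
#' arguments; safe across the antimeridian whether longitudes are given in
#' \[-180, 180\] or \[0, 360).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 1, 0)    # one degree of longitude at the equator
#' great_circle_km(179.5, -22, -179.5, -22)  # crosses the antimeridian
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90))
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Consecutive great-circle leg lengths (km) of a lon/lat sequence.
leg_lengths_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  great_circle_km(lon[-n], lat[-n], lon[-1], lat[-1])
}

# Keep longitudes on [0, 360) so tracks spanning 160E-175W stay contiguous.
wrap_lon_360 <- function(lon) lon %% 360

# Split R-hat (potential scale reduction) over a draws matrix with one column
# per chain; each chain is split in half to catch within-chain drift.
split_rhat <- function(draws) {
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    n <- floor(length(x) / 2)
    cbind(x[seq_len(n)], x[n + seq_len(n)])
  }))
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  B <- n * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
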