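# Habitat covariates: depth and isobath distances at each regularized
# location, ARS-versus-transit one-way ANOVAs, and proximity summaries
# around named shallow features.

#' Extract an isobath as polylines
#'
#' Marching-squares contour of the depth field at `-level_m` (depths are
#' negative-down), via [grDevices::contourLines].
#'
#' @param bathy a [bathymetry_grid()].
#' @param level_m isobath magnitude in metres (e.g. 200).
#' @return list of data.frames with `lon`, `lat` vertices.
#' @export
isobath_contours <- function(bathy, level_m) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  cl <- contourLines(bathy$lon_axis, bathy$lat_axis, bathy$depth,
                     levels = -abs(level_m))
  if (length(cl) == 0) {
    stop("isobath not present in raster: ", -abs(level_m), " m")
  }
  lapply(cl, function(c1) data.frame(lon = c1$x, lat = c1$y))
}

#' Distance to an isobath
#'
#' Minimum great-circle distance from each query point to the level-set
#' polyline of the depth field at `-level_m` (vertices and segment
#' interiors both considered; nearest contour anywhere in the raster).
#'
#' @param bathy a [bathymetry_grid()].
#' @param lon,lat query coordinates, degrees (vectorised).
#' @param level_m isobath magnitude, metres.
#' @return distances in km.
#' @export
distance_to_isobath <- function(bathy, lon, lat, level_m) {
  contours <- isobath_contours(bathy, level_m)
  pts <- cbind(wrap_to_axis(lon, bathy$lon_axis), lat)
  vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(contours, function(cc) {
      min_dist_to_polyline_km(pts[i, 1], pts[i, 2], cc$lon, cc$lat)
    }, 0))
  }, 0)
}

# Minimum distance (km) from a point to a polyline: project into a local
# tangent plane at the query point, take exact planar point-to-segment
# minima. Adequate at isobath-distance scales (well under basin scale).
min_dist_to_polyline_km <- function(plon, plat, vlon, vlat) {
  to_rad <- pi / 180
  dlon <- (vlon - plon + 180) %% 360 - 180
  x <- dlon * to_rad * EARTH_RADIUS_KM * cos(plat * to_rad)
  y <- (vlat - plat) * to_rad * EARTH_RADIUS_KM
  n <- length(x)
  d2 <- x^2 + y^2
  best <- min(d2)
  if (n > 1) {
    ax <- x[-n]; ay <- y[-n]; bx <- x[-1]; by <- y[-1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, pmax(0, pmin(1, -(ax * dx + ay * dy) / len2)), 0)
    qx <- ax + t * dx; qy <- ay + t * dy
    best <- min(best, qx^2 + qy^2)
  }
  sqrt(best)
}

#' Attach habitat covariates to regularized locations
#'
#' Samples depth and distances to the 200-m and 500-m isobaths at each
#' location.
#'
#' @param locations regularized locations (`whale_id`, `time_h`, `lon`,
#'   `lat`, `mode`).
#' @param bathy a [bathymetry_grid()] covering the locations.
#' @param isobaths isobath magnitudes, metres.
#' @return data.frame of habitat records: the input columns plus `depth_m`
#'   (negative-down) and one `dist_<level>m_km` column per isobath.
#' @export
habitat_records <- function(locations, bathy, isobaths = c(200, 500)) {
  out <- locations
  out$depth_m <- sample_depth(bathy, locations$lon, locations$lat)
  for (lv in isobaths) {
    out[[sprintf("dist_%dm_km", lv)]] <-
      distance_to_isobath(bathy, locations$lon, locations$lat, lv)
  }
  out
}

#' Compare ARS and transit habitats
#'
#' One-way ANOVA of each covariate on behavioural mode, using ARS and
#' transit locations only (uncertain-mode records are excluded). Depth is
#' compared as positive magnitude, the convention of habitat summaries.
#' If either mode is empty, group summaries are returned without a test,
#' with a warning.
#'
#' @param records [habitat_records()] output (needs `mode`, `depth_m`, and
#'   `dist_*_km` columns).
#' @param covariates columns to compare; default depth plus every
#'   `dist_*_km` column present.
#' @return data.frame, one row per covariate x mode, with group `mean`,
#'   `sd`, `n` and (on the first row of each covariate) `F` and `p`.
#' @export
compare_modes <- function(records, covariates = NULL) {
  rec <- records[records$mode %in% c("ARS", "transit"), , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- c("depth_m", grep("^dist_.*_km$", names(records),
                                    value = TRUE))
  }
  empty_out <- data.frame(covariate = character(0), mode = character(0),
                          mean = numeric(0), sd = numeric(0), n = integer(0),
                          F = numeric(0), p = numeric(0))
  if (nrow(rec) == 0) {
    warning("no ARS or transit records: nothing to summarize")
    return(empty_out)
  }
  both <- length(unique(rec$mode)) == 2 && all(table(rec$mode) >= 2)
  if (!both) {
    warning("need >= 2 records in each of ARS and transit for a test; ",
            "returning summaries only")
  }
  rows <- lapply(covariates, function(cv) {
    vals <- rec[[cv]]
    if (cv == "depth_m") vals <- abs(vals)
    sm <- do.call(rbind, lapply(split(vals, rec$mode), function(v) {
      data.frame(mean = mean(v), sd = sd(v), n = length(v))
    }))
    sm$covariate <- cv
    sm$mode <- rownames(sm)
    sm$F <- NA_real_; sm$p <- NA_real_
    if (both) {
      tab <- stats::anova(lm(vals ~ factor(rec$mode)))
      sm$F[1] <- tab$`F value`[1]
      sm$p[1] <- tab$`Pr(>F)`[1]
    }
    sm
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("covariate", "mode", "mean", "sd", "n", "F", "p")]
}

#' Behavioural-mode mix near named features
#'
#' A location is "near" if it lies within `radius_km` of any site. Returns
#' the fraction of near locations in each mode (fractions sum to 1), or an
#' all-`NA` row if no location is near any site.
#'
#' @param locations regularized locations with `mode`.
#' @param sites data.frame of features: `name`, `lon`, `lat`, optionally
#'   `radius_km` per site.
#' @param radius_km default association radius, km.
#' @return one-row data.frame: `n_near`, `frac_ARS`, `frac_transit`,
#'   `frac_uncertain`.
#' @export
feature_proximity_summary <- function(locations, sites, radius_km = 50) {
  stopifnot(nrow(sites) > 0)
  near <- rep(FALSE, nrow(locations))
  for (k in seq_len(nrow(sites))) {
    r <- if (!is.null(sites$radius_km)) sites$radius_km[k] else radius_km
    near <- near | great_circle_km(locations$lon, locations$lat,
                                   sites$lon[k], sites$lat[k]) <= r
  }
  if (!any(near)) {
    return(data.frame(n_near = 0L, frac_ARS = NA_real_,
                      frac_transit = NA_real_, frac_uncertain = NA_real_))
  }
  m <- locations$mode[near]
  data.frame(n_near = sum(near),
             frac_ARS = mean(m == "ARS"),
             frac_transit = mean(m == "transit"),
             frac_uncertain = mean(m == "uncertain"))
}
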