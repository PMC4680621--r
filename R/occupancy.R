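# Occupancy-time gridding: 10x10 km cells over an equal-area projection of
# the regularized locations, occupancy in days/whale, plus consecutive
# residence times near named features (seamounts, knolls, banks).

#' Project lon/lat to a local equal-area plane (km)
#'
#' Lambert cylindrical equal-area projection with the standard latitude at
#' the data centroid: x = R cos(lat_s) lon_rad, y = R sin(lat) / cos(lat_s).
#' Being exactly equal-area, every grid cell drawn on this plane covers the
#' same ocean area regardless of latitude.
#'
#' @param lon,lat coordinates, degrees.
#' @param lat_s standard latitude, degrees.
#' @param lon_0 central longitude, degrees.
#' @return data.frame `x`, `y` in km.
#' @export
project_equal_area <- function(lon, lat, lat_s, lon_0) {
  to_rad <- pi / 180
  dlon <- (lon - lon_0)
  dlon <- (dlon + 180) %% 360 - 180  # shortest way around
  cs <- cos(lat_s * to_rad)
  data.frame(x = EARTH_RADIUS_KM * cs * dlon * to_rad,
             y = EARTH_RADIUS_KM * sin(lat * to_rad) / cs)
}

#' Build an occupancy-time grid
#'
#' Bins all whales' regularized 12-h locations into square cells on an
#' equal-area projection centred on the data extent. Each cell records the
#' number of positions, the number of distinct whales that visited it, and
#' the occupancy time in days/whale: positions x 12 h / 24 / whales. A
#' whale revisiting a cell in separate passes still counts once. Cells
#' nobody visited are absent. Cell edges are half-open with the lower-left
#' edge inclusive.
#'
#' @param locations regularized locations for all whales (`whale_id`,
#'   `time_h`, `lon`, `lat`).
#' @param cell_size_km cell side, km (10 by default).
#' @param step_hours time represented by one location (12 h).
#' @return an `occupancy_grid`: data.frame with `cell_i`, `cell_j`,
#'   `center_lon`, `center_lat`, `n_positions`, `n_whales`,
#'   `days_per_whale`, plus attributes `cell_size_km`, `lat_s`, `lon_0`.
#' @export
build_occupancy <- function(locations, cell_size_km = 10, step_hours = 12) {
  if (nrow(locations) == 0) {
    out <- data.frame(cell_i = integer(0), cell_j = integer(0),
                      center_lon = numeric(0), center_lat = numeric(0),
                      n_positions = integer(0), n_whales = integer(0),
                      days_per_whale = numeric(0))
    return(structure(out, class = c("occupancy_grid", "data.frame"),
                     cell_size_km = cell_size_km, lat_s = NA, lon_0 = NA))
  }
  lat_s <- mean(range(locations$lat))
  lon_0 <- mean(range(unwrap_lon(locations$lon)))
  xy <- project_equal_area(locations$lon, locations$lat, lat_s, lon_0)
  # anchor the mesh at the lower-left of the data so clusters never
  # straddle the origin by construction
  x0 <- min(xy$x); y0 <- min(xy$y)
  ci <- floor((xy$x - x0) / cell_size_km)
  cj <- floor((xy$y - y0) / cell_size_km)
  key <- paste(ci, cj)
  parts <- split(seq_len(nrow(locations)), key)
  rows <- lapply(parts, function(idx) {
    data.frame(cell_i = ci[idx[1]], cell_j = cj[idx[1]],
               n_positions = length(idx),
               n_whales = length(unique(locations$whale_id[idx])))
  })
  out <- do.call(rbind, rows)
  # cell centres back-projected to lon/lat
  cs <- cos(lat_s * pi / 180)
  cx <- x0 + (out$cell_i + 0.5) * cell_size_km
  cy <- y0 + (out$cell_j + 0.5) * cell_size_km
  out$center_lon <- wrap_lon_360(lon_0 + cx / (EARTH_RADIUS_KM * cs) * 180 / pi)
  out$center_lat <- asin(pmax(-1, pmin(1, cy * cs / EARTH_RADIUS_KM))) * 180 / pi
  out$days_per_whale <- out$n_positions * step_hours / 24 / out$n_whales
  out <- out[order(out$cell_i, out$cell_j),
             c("cell_i", "cell_j", "center_lon", "center_lat",
               "n_positions", "n_whales", "days_per_whale")]
  rownames(out) <- NULL
  structure(out, class = c("occupancy_grid", "data.frame"),
            cell_size_km = cell_size_km, lat_s = lat_s, lon_0 = lon_0,
            origin_x = x0, origin_y = y0)
}

#' Consecutive residence times near a feature
#'
#' A stay is a maximal run of consecutive 12-h locations within
#' `radius_km` of the site; its duration is run length x 0.5 days. All
#' stays are returned, longest first, so the head of the result is the
#' longest continuous association with the feature.
#'
#' @param locations one whale's time-sorted regularized locations.
#' @param site list or one-row data.frame with `lon`, `lat` and optionally
#'   `radius_km`.
#' @param radius_km association radius, km (50 by default, overridden by
#'   the site's own radius if present).
#' @param step_hours grid spacing, hours.
#' @return numeric vector of stay durations in days (possibly empty).
#' @export
residence_time_days <- function(locations, site, radius_km = 50,
                                step_hours = 12) {
  r <- if (!is.null(site$radius_km)) site$radius_km else radius_km
  stopifnot(r > 0)
  if (nrow(locations) == 0) return(numeric(0))
  inside <- great_circle_km(locations$lon, locations$lat,
                            site$lon, site$lat) <= r
  runs <- rle(inside)
  stays <- runs$lengths[runs$values] * step_hours / 24
  sort(stays, decreasing = TRUE)
}

#' Export an occupancy grid
#'
#' Writes the grid as CSV and, optionally, as GeoJSON polygons (cell
#' outlines back-projected to lon/lat) for mapping.
#'
#' @param grid an `occupancy_grid`.
#' @param csv_path CSV output path.
#' @param geojson_path optional GeoJSON output path.
#' @return `csv_path`, invisibly.
#' @export
write_occupancy <- function(grid, csv_path, geojson_path = NULL) {
  write.csv(as.data.frame(grid), csv_path, row.names = FALSE)
  if (!is.null(geojson_path)) {
    cs <- attr(grid, "cell_size_km")
    lat_s <- attr(grid, "lat_s"); lon_0 <- attr(grid, "lon_0")
    csl <- cos(lat_s * pi / 180)
    unproject <- function(x, y) {
      lon <- lon_0 + x / (EARTH_RADIUS_KM * csl) * 180 / pi
      lat <- asin(pmax(-1, pmin(1, y * csl / EARTH_RADIUS_KM))) * 180 / pi
      c(wrap_lon_360(lon), lat)
    }
    ox <- attr(grid, "origin_x") %||% 0
    oy <- attr(grid, "origin_y") %||% 0
    feats <- lapply(seq_len(nrow(grid)), function(k) {
      x0 <- ox + grid$cell_i[k] * cs; y0 <- oy + grid$cell_j[k] * cs
      ring <- lapply(list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                          c(x0, y0 + cs), c(x0, y0)),
                     function(p) unproject(p[1], p[2]))
      list(type = "Feature",
           properties = list(n_positions = grid$n_positions[k],
                             n_whales = grid$n_whales[k],
                             days_per_whale = grid$days_per_whale[k]),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
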