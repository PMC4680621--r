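# Bathymetry grids: synthetic seamount-bearing rasters (the test path,
# standing in for ETOPO-style global relief), plain-text IO, and bilinear
# depth sampling. Depths are stored negative below sea level, ETOPO-style.

#' Construct a bathymetry grid object
#'
#' @param lon_axis,lat_axis strictly increasing coordinate vectors, degrees.
#' @param depth matrix `length(lon_axis) x length(lat_axis)`, metres,
#'   negative below sea level.
#' @return object of class `bathymetry_grid`.
#' @export
bathymetry_grid <- function(lon_axis, lat_axis, depth) {
  stopifnot(all(diff(lon_axis) > 0), all(diff(lat_axis) > 0),
            is.matrix(depth),
            nrow(depth) == length(lon_axis),
            ncol(depth) == length(lat_axis))
  structure(list(lon_axis = lon_axis, lat_axis = lat_axis, depth = depth),
            class = "bathymetry_grid")
}

#' Synthesize a seamount-bearing bathymetry raster
#'
#' Builds a flat abyssal floor with Gaussian seamount bumps: depth at
#' distance `r` km from a seamount centre is
#' `floor + (summit - floor) * exp(-r^2 / (2 * radius^2))`, so the raster
#' equals `floor_depth` far from any feature and rises smoothly to exactly
#' `summit_depth` at each centre. The closed-form level-set radius of an
#' isobath `L` around an isolated seamount is
#' `radius * sqrt(2 * log((summit - floor) / (L - floor)))` (depths signed),
#' which the tests exploit.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`, degrees; longitudes
#'   on \[0, 360) are accepted.
#' @param resolution grid spacing, degrees.
#' @param floor_depth abyssal depth, metres (negative, e.g. -3000).
#' @param seamounts data.frame with columns `lon`, `lat`, `summit_depth`
#'   (metres, negative, shallower than the floor), `radius_km`; or NULL for
#'   a featureless floor.
#' @return a [bathymetry_grid()].
#' @export
make_bathymetry <- function(extent, resolution = 0.1, floor_depth = -3000,
                            seamounts = NULL) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            floor_depth < 0)
  lon_axis <- seq(extent[1], extent[2], by = resolution)
  lat_axis <- seq(extent[3], extent[4], by = resolution)
  depth <- matrix(floor_depth, length(lon_axis), length(lat_axis))
  if (!is.null(seamounts) && nrow(seamounts) > 0) {
    if (any(seamounts$summit_depth <= floor_depth)) {
      stop("config error in 'seamounts': summit_depth must be shallower ",
           "(less negative) than floor_depth")
    }
    grid_lon <- matrix(lon_axis, length(lon_axis), length(lat_axis))
    grid_lat <- matrix(lat_axis, length(lon_axis), length(lat_axis),
                       byrow = TRUE)
    for (k in seq_len(nrow(seamounts))) {
      r <- great_circle_km(grid_lon, grid_lat,
                           seamounts$lon[k], seamounts$lat[k])
      bump <- (seamounts$summit_depth[k] - floor_depth) *
        exp(-r^2 / (2 * seamounts$radius_km[k]^2))
      depth <- pmax(depth, floor_depth + bump)
    }
  }
  bathymetry_grid(lon_axis, lat_axis, depth)
}

#' Sample depth by bilinear interpolation
#'
#' @param bathy a [bathymetry_grid()].
#' @param lon,lat query coordinates, degrees (vectorised).
#' @return depth in metres (negative below sea level).
#' @export
sample_depth <- function(bathy, lon, lat) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  lon <- wrap_to_axis(lon, bathy$lon_axis)
  out_of <- lon < bathy$lon_axis[1] | lon > bathy$lon_axis[length(bathy$lon_axis)] |
    lat < bathy$lat_axis[1] | lat > bathy$lat_axis[length(bathy$lat_axis)]
  if (any(out_of)) {
    stop("points outside raster extent: ",
         paste(sprintf("(%.3f, %.3f)", lon[out_of], lat[out_of]),
               collapse = ", "))
  }
  ix <- findInterval(lon, bathy$lon_axis, rightmost.closed = TRUE)
  iy <- findInterval(lat, bathy$lat_axis, rightmost.closed = TRUE)
  ix <- pmin(ix, length(bathy$lon_axis) - 1)
  iy <- pmin(iy, length(bathy$lat_axis) - 1)
  x0 <- bathy$lon_axis[ix]; x1 <- bathy$lon_axis[ix + 1]
  y0 <- bathy$lat_axis[iy]; y1 <- bathy$lat_axis[iy + 1]
  tx <- (lon - x0) / (x1 - x0)
  ty <- (lat - y0) / (y1 - y0)
  d00 <- bathy$depth[cbind(ix, iy)]
  d10 <- bathy$depth[cbind(ix + 1, iy)]
  d01 <- bathy$depth[cbind(ix, iy + 1)]
  d11 <- bathy$depth[cbind(ix + 1, iy + 1)]
  (1 - tx) * (1 - ty) * d00 + tx * (1 - ty) * d10 +
    (1 - tx) * ty * d01 + tx * ty * d11
}

# Match query longitudes to the raster's longitude convention (0..360 vs
# -180..180) before range checks.
wrap_to_axis <- function(lon, lon_axis) {
  lo <- lon_axis[1]; hi <- lon_axis[length(lon_axis)]
  cand <- cbind(lon, lon - 360, lon + 360)
  pick <- apply(cand, 1, function(v) {
    inside <- v >= lo & v <= hi
    if (any(inside)) v[inside][1] else v[1]
  })
  as.numeric(pick)
}

#' Write / read a bathymetry grid as plain text
#'
#' A dependency-free text format: a 6-line header (`ncols`, `nrows`,
#' `lon_start`, `lat_start`, `cellsize`, `nodata`) followed by the depth
#' matrix, one latitude row per line, northernmost first (ESRI ASCII grid
#' layout).
#'
#' @param bathy a [bathymetry_grid()].
#' @param path output file.
#' @return `write_bathymetry_ascii`: the path, invisibly.
#' @export
write_bathymetry_ascii <- function(bathy, path) {
  stopifnot(inherits(bathy, "bathymetry_grid"))
  res <- diff(bathy$lon_axis[1:2])
  hdr <- c(paste("ncols", length(bathy$lon_axis)),
           paste("nrows", length(bathy$lat_axis)),
           paste("lon_start", format(bathy$lon_axis[1], digits = 12)),
           paste("lat_start", format(bathy$lat_axis[1], digits = 12)),
           paste("cellsize", format(res, digits = 12)),
           "nodata -99999")
  rows <- apply(t(bathy$depth)[rev(seq_along(bathy$lat_axis)), , drop = FALSE],
                1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_bathymetry_ascii
#' @return `read_bathymetry_ascii`: a [bathymetry_grid()].
#' @export
read_bathymetry_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- setNames(vapply(hdr, function(x) x[2], ""),
                   vapply(hdr, function(x) x[1], ""))
  ncols <- as.integer(vals["ncols"]); nrows <- as.integer(vals["nrows"])
  lon0 <- as.numeric(vals["lon_start"]); lat0 <- as.numeric(vals["lat_start"])
  cs <- as.numeric(vals["cellsize"])
  depth_rows <- do.call(rbind, lapply(lines[7:(6 + nrows)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  depth <- t(depth_rows[rev(seq_len(nrows)), , drop = FALSE])
  bathymetry_grid(lon0 + (seq_len(ncols) - 1) * cs,
                  lat0 + (seq_len(nrows) - 1) * cs, depth)
}
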