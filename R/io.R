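# CSV interchange: Argos fixes (ptt, ISO-8601 UTC timestamp, lc, lon, lat),
# regularized locations, and the published per-whale tracking summary
# bundled as reference data.

#' Write / read Argos fixes as CSV
#'
#' The interchange dialect is one row per fix with columns `ptt`,
#' `timestamp` (ISO-8601 UTC), `lc`, `lon`, `lat`. Internally the package
#' keeps time as hours since deployment; `origin` fixes the epoch used for
#' the conversion.
#'
#' @param fixes data.frame with `ptt`, `time_h`, `lc`, `lon`, `lat`.
#' @param path file path.
#' @param origin POSIXct epoch that `time_h` counts from.
#' @return the path (write) or a fixes data.frame with `time_h` (read).
#' @export
write_argos_csv <- function(fixes, path,
                            origin = as.POSIXct("2010-08-01 00:00:00",
                                                tz = "UTC")) {
  out <- data.frame(
    ptt = fixes$ptt,
    timestamp = format(origin + fixes$time_h * 3600, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    lc = fixes$lc, lon = fixes$lon, lat = fixes$lat)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_argos_csv
#' @export
read_argos_csv <- function(path,
                           origin = as.POSIXct("2010-08-01 00:00:00",
                                               tz = "UTC")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.frame(ptt = as.character(d$ptt),
             time_h = as.numeric(difftime(ts, origin, units = "hours")),
             lc = as.character(d$lc), lon = d$lon, lat = d$lat,
             stringsAsFactors = FALSE)
}

#' Write regularized locations as CSV
#'
#' Columns `whale_id`, `time_h`, `lon`, `lat`, `b_mean`, `mode` — the
#' interchange format consumed by the metrics, occupancy and habitat
#' stages.
#'
#' @param locations regularized-location data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_locations_csv <- function(locations, path) {
  write.csv(locations[, c("whale_id", "time_h", "lon", "lat",
                          "b_mean", "mode")], path, row.names = FALSE)
  invisible(path)
}

#' Published humpback tracking summary
#'
#' Loads the bundled per-whale summary of the 34 humpback whales
#' satellite-tagged off New Caledonia (2007-2012): tag duration, sex,
#' social category, minimum total distance and mean speeds (overall /
#' breeding-ground / migratory, km/h, 1 decimal), and the percentage of
#' 12-h locations classified as ARS / transiting / uncertain. `NA` in a
#' speed column means the value was not estimable (fewer than 10 locations
#' in the phase) or the phase did not occur.
#'
#' Useful as a worked-example input: for rows where the printed mean speed
#' equals minimum distance / elapsed time at 1-decimal rounding, the
#' package's speed metrics reproduce the printed value exactly.
#'
#' @return data.frame, one row per whale.
#' @export
nc_tracking_summary <- function() {
  path <- system.file("extdata", "nc_humpback_tracking_summary.csv",
                      package = "whaletrackr")
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(ptt = "character"))
}
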