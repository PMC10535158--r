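#' GPS fixes and vessel speed
#'
#' The onboard device does not process video in real time. A scheduler
#' watches the GPS stream: below 4 knots the boat is assumed to be
#' fishing and the device only records; at 4 knots or above — or within
#' a configured radius of the home port — it is travelling or docked,
#' and switches to processing the stored video.
#'
#' @param timestamp seconds (monotone within a track)
#' @param lat,lon degrees
#' @return `gps_fix()`: a list of class `gps_fix`
#' @export
gps_fix <- function(timestamp, lat, lon) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180)
  structure(list(timestamp = timestamp, lat = lat, lon = lon),
            class = "gps_fix")
}

# mean Earth radius (m), shared by speed and geofence calculations
EARTH_RADIUS_M <- 6371008.8

#' @rdname gps_fix
#' @param lat1,lon1,lat2,lon2 coordinates in degrees
#' @return `haversine_m()`: great-circle distance in metres
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Speed between two GPS fixes, in knots
#'
#' Great-circle distance over elapsed time, converted to knots
#' (1 knot = 1852 m per hour). Symmetric in position and non-negative.
#'
#' @param a,b [gps_fix()]es with `b$timestamp > a$timestamp`
#' @return speed in knots
#' @export
speed_knots <- function(a, b) {
  dt <- b$timestamp - a$timestamp
  if (dt <= 0) stop("timestamps must be strictly increasing")
  dist_m <- haversine_m(a$lat, a$lon, b$lat, b$lon)
  (dist_m / dt) * 3600 / 1852
}

#' Scheduler configuration
#'
#' @param speed_threshold knots separating fishing from travelling
#'   (default 4)
#' @param port_center `c(lat, lon)` of the home port, or `NULL` if no
#'   geofence is configured
#' @param port_radius geofence radius in metres
#' @return object of class `scheduler_config`
#' @export
scheduler_config <- function(speed_threshold = 4.0, port_center = NULL,
                             port_radius = NULL) {
  stopifnot(speed_threshold > 0)
  if (!is.null(port_radius)) stopifnot(port_radius > 0)
  structure(list(speed_threshold = speed_threshold,
                 port_center = port_center, port_radius = port_radius),
            class = "scheduler_config")
}

#' Decide the operating state from a pair of GPS fixes
#'
#' Returns `"RECORD"` while fishing (speed below the threshold and
#' outside the port radius) and `"PROCESS"` when travelling or docked
#' (speed at or above the threshold, *or* inside the port radius). A
#' speed exactly at the threshold maps to `PROCESS`. Without a port
#' configuration the speed rule alone applies, with a warning.
#'
#' @param a,b consecutive [gps_fix()]es
#' @param config a [scheduler_config()]
#' @return `"RECORD"` or `"PROCESS"`
#' @export
operating_state <- function(a, b, config = scheduler_config()) {
  spd <- speed_knots(a, b)
  in_port <- FALSE
  if (is.null(config$port_center) || is.null(config$port_radius)) {
    warning("no port configured; applying speed rule only")
  } else {
    d <- haversine_m(b$lat, b$lon,
                     config$port_center[1L], config$port_center[2L])
    in_port <- d <= config$port_radius
  }
  operating_state_speed(spd, in_port, config)
}

#' @rdname operating_state
#' @param speed speed in knots
#' @param in_port whether the latest fix lies inside the port geofence
#' @details `operating_state_speed()` is the bare decision rule on an
#'   already-computed speed; a speed exactly equal to the threshold maps
#'   to `PROCESS`.
#' @export
operating_state_speed <- function(speed, in_port = FALSE,
                                  config = scheduler_config()) {
  stopifnot(speed >= 0)
  if (speed >= config$speed_threshold || in_port) "PROCESS" else "RECORD"
}

#' Median-smoothed speeds along a GPS track
#'
#' Per-pair speeds are noisy under GPS jitter; a running median of `k`
#' consecutive pair speeds (default 3) is used before comparing against
#' the threshold.
#'
#' @param track data.frame with `timestamp`, `lat`, `lon` (one row per
#'   fix, timestamps strictly increasing)
#' @param k odd median window; 1 disables smoothing
#' @return numeric vector of `nrow(track) - 1` speeds in knots
#' @export
track_speeds <- function(track, k = 3) {
  stopifnot(nrow(track) >= 2L, k >= 1, k %% 2 == 1)
  if (any(diff(track$timestamp) <= 0))
    stop("timestamps must be strictly increasing")
  n <- nrow(track) - 1L
  raw <- vapply(seq_len(n), function(i) {
    speed_knots(gps_fix(track$timestamp[i], track$lat[i], track$lon[i]),
                gps_fix(track$timestamp[i + 1L], track$lat[i + 1L],
                        track$lon[i + 1L]))
  }, numeric(1))
  if (k == 1 || n < k) return(raw)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    median(raw[lo:hi])
  }, numeric(1))
}

#' @rdname track_speeds
#' @param path CSV file with columns `timestamp,lat,lon`
#' @export
read_gps_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("timestamp", "lat", "lon") %in% names(df)))
  df
}
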