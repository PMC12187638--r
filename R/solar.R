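#' Solar position helpers
#'
#' A longitude-free local-clock approximation of solar geometry: solar noon is
#' assumed to fall at 12:00 local standard time, and solar declination follows
#' the usual cosine approximation of the Earth's axial tilt. This is accurate
#' to within a few minutes of true sunrise/sunset at mid-latitudes, which is
#' ample for masking logger records to daylight.
#'
#' @name solar
#' @keywords internal
NULL

# solar declination (radians) for a day-of-year
solar_declination <- function(doy) {
  -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365.25)
}

# sine of solar elevation at fractional hour `hour` (local standard time)
solar_sin_elevation <- function(doy, hour, latitude) {
  decl <- solar_declination(doy)
  lat <- latitude * pi / 180
  hour_angle <- (hour - 12) * 15 * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
}

#' Daylight mask for a timestamp vector
#'
#' Flags the timestamps at which the sun is above the horizon at the given
#' latitude. Timestamps are interpreted as local standard time; solar noon is
#' taken as 12:00 (no longitude/equation-of-time correction, configurable via
#' `clock_offset`).
#'
#' @param timestamps a `POSIXct` vector (local standard time).
#' @param site_latitude latitude in decimal degrees; must satisfy
#'   `abs(site_latitude) <= 66.5` (polar day/night is out of scope).
#' @param clock_offset hours to add to the clock time before computing solar
#'   position (default 0).
#' @return a logical vector, `TRUE` where solar elevation is positive.
#' @examples
#' ts <- seq(as.POSIXct("2019-03-21 00:00", tz = "UTC"),
#'           by = "30 min", length.out = 48)
#' sum(daytime_mask(ts, -32.3)) # about 24 half-hour ticks near the equinox
#' @export
daytime_mask <- function(timestamps, site_latitude, clock_offset = 0) {
  stopifnot(inherits(timestamps, "POSIXct"))
  if (!is.finite(site_latitude) || abs(site_latitude) > 66.5) {
    stop("`site_latitude` must lie within [-66.5, 66.5] degrees", call. = FALSE)
  }
  lt <- as.POSIXlt(timestamps)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600 + clock_offset
  solar_sin_elevation(doy, hour, site_latitude) > 0
}

# sunrise/sunset fractional hours for a day-of-year; NA when the sun never
# rises/sets (excluded upstream by the latitude check)
sunrise_sunset <- function(doy, latitude) {
  decl <- solar_declination(doy)
  lat <- latitude * pi / 180
  cos_h0 <- -tan(lat) * tan(decl)
  cos_h0 <- pmin(1, pmax(-1, cos_h0))
  h0 <- acos(cos_h0) * 180 / pi / 15 # half day length in hours
  list(sunrise = 12 - h0, sunset = 12 + h0)
}
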