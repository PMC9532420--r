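# Solar geometry: declination, twilight azimuths and the angular speed of
# sun azimuth near sunrise/sunset.

#' Solar declination from day of year
#'
#' Smooth annual cosine approximation
#' \eqn{\delta_s = -23.44^\circ \cos(2\pi (d + 10)/365)}: zero near the
#' equinoxes (crossings ~Mar 22, ~Sep 21) and \eqn{\pm 23.44^\circ} at the solstices,
#' within about half a degree of almanac values. Days outside [1, 365] wrap
#' around the year.
#'
#' @param day_of_year integer day (1 = Jan 1; values > 365 wrap).
#' @return solar declination in degrees.
#' @export
solar_declination <- function(day_of_year) {
  d <- ((day_of_year - 1) %% 365) + 1
  -23.44 * cos(2 * pi * (d + 10) / 365)
}

# internal: sunset azimuth in radians from the S axis (same clockwise sense
# as headings); NA where the sun does not rise/set. delta, phi in radians.
.theta_s_rad <- function(phi, delta) {
  x <- -sin(delta) / cos(phi)
  out <- rep(NA_real_, length(x))
  ok <- abs(x) <= 1
  out[ok] <- acos(x[ok])
  out
}

#' Sunset (or sunrise) azimuth
#'
#' Closed-form twilight azimuth
#' \deqn{\theta_s = \cos^{-1}\left(-\sin\delta_s / \cos\phi\right),}
#' measured from the geographic N-S axis in the same clockwise sense as
#' headings. The positive solution is the sunset azimuth; the sunrise
#' azimuth is its negative.
#'
#' @param lat_deg latitude in degrees.
#' @param day_of_year day of year (used to compute the declination) --
#'   alternatively supply `delta_deg` directly.
#' @param delta_deg solar declination in degrees (overrides `day_of_year`).
#' @param twilight `"sunset"` (positive solution, default) or `"sunrise"`.
#' @return azimuth in degrees. Errors with condition class
#'   `compasscourse_polar_light` where the sun neither rises nor sets
#'   (polar day/night); callers use this to mask undefined regions.
#' @examples
#' sunset_azimuth(55, delta_deg = 17.9) # ~ 122.4
#' @export
sunset_azimuth <- function(lat_deg, day_of_year = NULL, delta_deg = NULL,
                           twilight = c("sunset", "sunrise")) {
  twilight <- match.arg(twilight)
  if (is.null(delta_deg)) {
    if (is.null(day_of_year)) stop("supply `day_of_year` or `delta_deg`")
    delta_deg <- solar_declination(day_of_year)
  }
  th <- .theta_s_rad(.rad(lat_deg), .rad(delta_deg))
  if (any(is.na(th))) {
    stop(structure(
      class = c("compasscourse_polar_light", "error", "condition"),
      list(message = "no sunset/sunrise at this latitude and date (polar day or night)",
           call = sys.call())
    ))
  }
  if (twilight == "sunset") .deg(th) else -.deg(th)
}

#' Angular speed of sun azimuth at twilight
#'
#' Near sunrise and sunset the sun's azimuth crosses the horizon at the
#' latitude-only rate \eqn{\partial\theta_s/\partial h \approx 2\pi\sin\phi/24}
#' per hour, i.e. 15 deg/h times \eqn{\sin\phi}. This is the
#' time-compensation rate used by the time-compensated sun compass.
#'
#' @param lat_deg latitude in degrees (|lat| < 90).
#' @return angular speed in degrees per hour.
#' @export
azimuth_speed <- function(lat_deg) {
  if (any(abs(lat_deg) >= 90)) stop("|lat| must be < 90")
  15 * sin(.rad(lat_deg))
}

#' Lowest latitude without sunset on a given day
#'
#' The no-sunset boundary \eqn{90^\circ - |\delta_s|} implied by the
#' sunset-azimuth formula (where \eqn{|\sin\delta_s| = \cos\phi}).
#'
#' @inheritParams solar_declination
#' @return boundary latitude in degrees.
#' @export
no_sunset_latitude <- function(day_of_year) {
  90 - abs(solar_declination(day_of_year))
}
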