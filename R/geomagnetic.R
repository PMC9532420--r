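# Geomagnetic cue fields: an axial dipole model (core) and a pluggable
# provider interface for real-field adapters.

#' Dipole geomagnetic field sample
#'
#' In an axial dipole the horizontal and vertical field components, and
#' hence the inclination, depend only on geomagnetic latitude:
#' \eqn{\gamma = \tan^{-1}(2\tan\phi_m)}, and magnetic declination is zero
#' everywhere. Declination is signed positive when magnetic South is
#' rotated clockwise from geographic South.
#'
#' @param lat_m_deg geomagnetic latitude in degrees.
#' @return list with `declination` (degrees, 0), `inclination` (degrees)
#'   and `magnetic_latitude` (degrees).
#' @examples
#' dipole_field(45)$inclination # ~ 63.43
#' @export
dipole_field <- function(lat_m_deg) {
  list(
    declination = rep(0, length(lat_m_deg)),
    inclination = .deg(atan(2 * tan(.rad(lat_m_deg)))),
    magnetic_latitude = lat_m_deg
  )
}

#' Construct a geomagnetic field provider
#'
#' A field provider is a function `(lat_deg, lon_deg, day)` returning a
#' list with `declination` and `inclination` (degrees). The built-in
#' `"dipole"` provider ignores longitude and date and interprets latitude
#' as geomagnetic latitude (generic-migrant simulations run entirely in the
#' magnetic frame). A `"real"` provider is an adapter contract for an
#' external spherical-harmonic field model: supply `fun(lat, lon,
#' decimal_year)` returning the same list; without one, calling the
#' provider is a configuration error.
#'
#' @param type `"dipole"` or `"real"`.
#' @param fun for `type = "real"`, the adapter function.
#' @param epoch_year decimal year passed to a real-field adapter (default
#'   2000.7, an autumn epoch).
#' @return a provider function with class `field_provider`.
#' @export
field_provider <- function(type = c("dipole", "real"), fun = NULL,
                           epoch_year = 2000.7) {
  type <- match.arg(type)
  if (type == "dipole") {
    p <- function(lat_deg, lon_deg = 0, day = NULL) dipole_field(lat_deg)
  } else {
    if (is.null(fun)) {
      p <- function(lat_deg, lon_deg = 0, day = NULL) {
        stop("real-field provider is not configured; pass `fun` to field_provider()")
      }
    } else {
      force(fun); force(epoch_year)
      p <- function(lat_deg, lon_deg = 0, day = NULL) {
        fun(lat_deg, lon_deg, epoch_year + if (is.null(day)) 0 else 0 * day)
      }
    }
  }
  structure(p, class = c("field_provider", "function"), provider_type = type)
}
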