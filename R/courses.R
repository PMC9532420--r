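# Expected (error-free) flight-step headings for the five compass courses,
# including time-compensated sun compass (TCSC) clock-shift bookkeeping.

.COURSES <- c("geographic_lox", "geomagnetic_lox", "magnetoclinic",
              "fixed_sun", "tcsc")

#' Specify a compass course
#'
#' Builds the imprinted constants a migrant fixes at migration onset from
#' its inherited initial heading `alpha0` and the natal conditions:
#' the transverse inclination projection for magnetoclinic courses
#' (via the natal geomagnetic latitude), and the sun-compass offset
#' \eqn{\bar\alpha_s = \bar\alpha_0 - \theta_{s,0}} for sun courses.
#'
#' @param course one of `"geographic_lox"`, `"geomagnetic_lox"`,
#'   `"magnetoclinic"`, `"fixed_sun"`, `"tcsc"`.
#' @param alpha0 inherited initial heading, degrees clockwise from
#'   geographic South.
#' @param natal_lat,natal_lon natal location, degrees (geomagnetic frame
#'   under the dipole provider).
#' @param depart_day day of year of migration onset (imprints the sunset
#'   azimuth for sun courses).
#' @param tcsc_variant clock handling for TCSC courses: `"classic"`
#'   (time-compensation rate retained from the last clock-reset site),
#'   `"proximate"` (rate gauged from the current site), or
#'   `"retain_first_night"` (reference heading frozen on the first night of
#'   each extended stopover).
#' @param transferred whether flight-step headings are transferred to and
#'   held on a secondary in-flight compass (default: `TRUE` for the sun
#'   courses, which night migrants must transfer; `FALSE` otherwise).
#' @param twilight `"sunset"` (night migrants) or `"sunrise"` (day
#'   migrants): which twilight azimuth solution the sun courses use.
#' @param provider a [field_provider()] (default dipole).
#' @param hemisphere `"N"` or `"S"` departure hemisphere; Southern
#'   departures mirror the heading axis.
#' @return object of class `course_spec`.
#' @export
course_spec <- function(course, alpha0, natal_lat, natal_lon = 0,
                        depart_day = 258,
                        tcsc_variant = c("classic", "proximate", "retain_first_night"),
                        transferred = NULL,
                        twilight = c("sunset", "sunrise"),
                        provider = field_provider("dipole"),
                        hemisphere = "N") {
  course <- match.arg(course, .COURSES)
  tcsc_variant <- match.arg(tcsc_variant)
  twilight <- match.arg(twilight)
  if (is.null(transferred)) transferred <- course %in% c("fixed_sun", "tcsc")
  spec <- list(course = course, alpha0 = alpha0,
               natal_lat = natal_lat, natal_lon = natal_lon,
               depart_day = depart_day, tcsc_variant = tcsc_variant,
               transferred = transferred, twilight = twilight,
               provider = provider, hemisphere = hemisphere)
  if (course == "magnetoclinic") {
    f0 <- provider(natal_lat, natal_lon, depart_day)
    spec$gamma0 <- f0$inclination
    spec$phi_m0 <- f0$magnetic_latitude %||% natal_lat
    if (abs(spec$phi_m0) < 1e-9) {
      stop("magnetoclinic imprinting undefined at the magnetic equator")
    }
  }
  if (course %in% c("fixed_sun", "tcsc")) {
    spec$theta_s0 <- sunset_azimuth(natal_lat, depart_day, twilight = twilight)
    spec$alpha_s <- alpha0 - spec$theta_s0
  }
  structure(spec, class = "course_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.course_spec <- function(x, ...) {
  cat(sprintf("<course_spec> %s  alpha0 %.1f deg  natal %.1f,%.1f  day %d%s%s\n",
              x$course, x$alpha0, x$natal_lat, x$natal_lon, x$depart_day,
              if (x$transferred) "  [cue-transferred]" else "",
              if (x$course == "tcsc") paste0("  variant=", x$tcsc_variant) else ""))
  invisible(x)
}

#' Expected headings for each compass course
#'
#' Error-free flight-step headings (degrees, clockwise from geographic
#' South). `heading_geographic_lox` returns the inherited heading
#' unchanged; `heading_geomagnetic_lox` offsets it by the proximate
#' magnetic declination; `heading_magnetoclinic` preserves the transverse
#' projection of the proximate inclination,
#' \deqn{\bar\alpha_i = \sin^{-1}(\tan\gamma_i \sin\bar\alpha_0 / \tan\gamma_0),}
#' heading due magnetic East or West (sign of \eqn{\sin\bar\alpha_0}) when
#' no solution exists, until inclination decreases sufficiently (a
#' `fallback` attribute flags this); `heading_fixed_sun` keeps a constant
#' offset to the proximate twilight azimuth.
#'
#' @param spec a [course_spec()].
#' @param lat_deg,lon_deg current location in degrees.
#' @param day current day of year.
#' @param declination_deg proximate magnetic declination (degrees; from the
#'   field provider if omitted).
#' @return heading in degrees; `heading_magnetoclinic` carries a logical
#'   `fallback` attribute.
#' @name course-headings
NULL

#' @rdname course-headings
#' @export
heading_geographic_lox <- function(spec) spec$alpha0

#' @rdname course-headings
#' @export
heading_geomagnetic_lox <- function(spec, lat_deg = NULL, lon_deg = 0,
                                    day = NULL, declination_deg = NULL) {
  if (is.null(declination_deg)) {
    declination_deg <- spec$provider(lat_deg, lon_deg, day)$declination
  }
  spec$alpha0 + declination_deg
}

# internal, radians: magnetoclinic in a dipole given tan(gamma)/tan(gamma0)
# expressed through magnetic latitudes. Returns list(alpha, fallback).
.magnetoclinic_rad <- function(sin_a0, phi_m0, phi_m) {
  arg <- sin_a0 * tan(phi_m) / tan(phi_m0)
  fb <- abs(arg) > 1
  alpha <- ifelse(fb, sign(sin_a0) * pi / 2, asin(pmin(1, pmax(-1, arg))))
  list(alpha = alpha, fallback = fb)
}

#' @rdname course-headings
#' @export
heading_magnetoclinic <- function(spec, lat_deg, lon_deg = 0, day = NULL) {
  f <- spec$provider(lat_deg, lon_deg, day)
  # general form via inclinations; equals the dipole closed form when the
  # provider is the dipole (tan gamma = 2 tan phi_m)
  arg <- tan(.rad(f$inclination)) * sin(.rad(spec$alpha0)) / tan(.rad(spec$gamma0))
  fb <- abs(arg) > 1
  alpha <- ifelse(fb, sign(sin(.rad(spec$alpha0))) * 90,
                  .deg(asin(pmin(1, pmax(-1, arg)))))
  structure(alpha, fallback = fb)
}

#' @rdname course-headings
#' @export
heading_fixed_sun <- function(spec, lat_deg, day) {
  spec$alpha_s + sunset_azimuth(lat_deg, day, twilight = spec$twilight)
}

#' Clock state of a time-compensated sun-compass migrant
#'
#' Reference quantities carried between flight-steps: the heading, twilight
#' azimuth and longitude at the most recent clock-reset site, and the
#' latitude whose twilight azimuth speed defines the time-compensation
#' rate (equal to the reset site for the classic variant; the current site
#' for the proximate variant).
#'
#' @param alpha_ref reference heading (degrees).
#' @param theta_ref twilight azimuth at the reference departure (degrees).
#' @param lambda_ref longitude at the clock-reset site (degrees).
#' @param sref_lat latitude defining the time-compensation rate (degrees).
#' @return list of class `clock_state`.
#' @export
clock_state <- function(alpha_ref, theta_ref, lambda_ref, sref_lat) {
  structure(list(alpha_ref = alpha_ref, theta_ref = theta_ref,
                 lambda_ref = lambda_ref, sref_lat = sref_lat),
            class = "clock_state")
}

#' Time-compensated sun-compass heading
#'
#' \deqn{\bar\alpha_i = \bar\alpha_{ref} + (\theta_{s,i} - \theta_{s,ref})
#'   + (\lambda_i - \lambda_{ref})\sin\phi_{s_{ref}},}
#' the reference heading plus the change in twilight azimuth since the
#' reference plus the clock-shift term from longitudinal displacement. The
#' clock-shift term opposes spurious longitude errors (self-correction):
#' an erroneous eastward displacement yields a westward heading offset.
#' For the `"proximate"` variant the rate latitude \eqn{\phi_{s_{ref}}} is
#' the current latitude.
#'
#' @inheritParams course-headings
#' @param clock a [clock_state()].
#' @return heading in degrees.
#' @export
heading_tcsc <- function(spec, clock, lat_deg, lon_deg, day) {
  th <- sunset_azimuth(lat_deg, day, twilight = spec$twilight)
  sref_lat <- if (spec$tcsc_variant == "proximate") lat_deg else clock$sref_lat
  dlam <- .deg(.wrap_pi(.rad(lon_deg - clock$lambda_ref)))
  clock$alpha_ref + (th - clock$theta_ref) + dlam * sin(.rad(sref_lat))
}

#' Predicted TCSC self-correction for a longitudinal displacement
#'
#' Small-displacement limit of the clock-shift heading offset:
#' \eqn{\Delta\bar\alpha \approx \Delta\lambda \sin\phi}.
#'
#' @param delta_lambda_deg longitudinal displacement in degrees (positive =
#'   eastward).
#' @param lat_deg latitude in degrees.
#' @return expected corrective heading offset in degrees (positive =
#'   westward heading shift, opposing an eastward displacement).
#' @examples
#' predicted_self_correction(28, 55) # ~ 23
#' @export
predicted_self_correction <- function(delta_lambda_deg, lat_deg) {
  delta_lambda_deg * sin(.rad(lat_deg))
}
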