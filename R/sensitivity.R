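# Analytic sensitivity of successive headings, d(alpha_i)/d(alpha_{i-1}),
# for each compass course, a central finite-difference oracle over the
# composed step + heading-rule map, and latitude x heading grids.
#
# Conventions: the state is the pre-step latitude phi_{i-1} and realized
# heading alpha_{i-1}; the successive expected heading alpha_i is evaluated
# at the post-step location phi_i = phi_{i-1} - R_step cos(alpha_{i-1}),
# which is what the analytic expressions differentiate (perturbations in
# alpha_{i-1} propagate through the planar step equations).

#' Sensitivity of loxodrome headings
#'
#' Constant-heading (geographic, or geomagnetic in a dipole) courses do not
#' depend on the previous heading: the sensitivity is identically zero, so
#' independent per-step errors neither grow nor self-correct.
#'
#' @return 0.
#' @export
sensitivity_loxodrome <- function() 0

#' Sensitivity of magnetoclinic headings (dipole field)
#'
#' Differentiating the dipole closed form through the step equations:
#' \deqn{\frac{d\bar\alpha_i}{d\alpha_{i-1}} =
#'  \frac{R_{step}\sin\alpha_{i-1}\,\sin\bar\alpha_0}
#'       {\cos\bar\alpha_i\,\cos^2\phi_{m,i}\,\tan\phi_{m,0}}.}
#' Because the course preserves \eqn{\sin\bar\alpha/\tan\phi_m}, the
#' imprinting constants default to the local state (`alpha0 = alpha_prev`,
#' `lat0 = lat`), which is how the latitude-by-heading grids are drawn.
#'
#' @param alpha_prev_deg realized heading at step i-1 (degrees from South).
#' @param lat_deg pre-step (geomagnetic) latitude in degrees.
#' @param r_step_km flight-step distance in km.
#' @param alpha0_deg,lat0_deg imprinted initial heading and geomagnetic
#'   latitude (default: the local state).
#' @return signed derivative (dimensionless); `NA` where the course rule
#'   has no solution (East/West fallback states).
#' @export
sensitivity_magnetoclinic <- function(alpha_prev_deg, lat_deg, r_step_km = 360,
                                      alpha0_deg = alpha_prev_deg,
                                      lat0_deg = lat_deg) {
  r <- r_step_km / R_EARTH
  a <- .rad(alpha_prev_deg); p0 <- .rad(lat0_deg)
  pi_ <- .rad(lat_deg) - r * cos(a)
  arg <- sin(.rad(alpha0_deg)) * tan(pi_) / tan(p0)
  bad <- abs(arg) >= 1 | abs(pi_) >= pi / 2
  ai <- asin(pmin(1, pmax(-1, arg)))
  out <- r * sin(a) * sin(.rad(alpha0_deg)) / (cos(ai) * cos(pi_)^2 * tan(p0))
  out[bad] <- NA_real_
  out
}

# internal: d(theta_s)/d(phi) in radians, NA where no twilight.
# theta = acos(-sin d / cos p) => dtheta/dphi = sin d sin p/(sin th cos^2 p)
.dtheta_dphi <- function(phi, delta) {
  th <- .theta_s_rad(phi, delta)
  sin(delta) * sin(phi) / (sin(th) * cos(phi)^2)
}

#' Sensitivity of fixed sun-compass headings
#'
#' The twilight azimuth depends on latitude, so
#' \deqn{\frac{d\bar\alpha_i}{d\alpha_{i-1}} =
#'   R_{step}\sin\alpha_{i-1}\,
#'   \frac{\sin\delta_s \sin\phi_i}{\sin\theta_{s,i}\cos^2\phi_i}
#'   = -R_{step}\sin\alpha_{i-1}\frac{\tan\phi_i}{\tan\theta_{s,i}}.}
#' Zero at the equinoxes (\eqn{\delta_s = 0}), with sign flipping between
#' East and West headings and across the fall equinox.
#'
#' @inheritParams sensitivity_magnetoclinic
#' @param day day of year.
#' @return signed derivative; `NA` where the sun does not set.
#' @export
sensitivity_fixed_sun <- function(alpha_prev_deg, lat_deg, day, r_step_km = 360) {
  r <- r_step_km / R_EARTH
  a <- .rad(alpha_prev_deg)
  pi_ <- .rad(lat_deg) - r * cos(a)
  d <- .rad(solar_declination(day))
  r * sin(a) * .dtheta_dphi(pi_, d)
}

#' Sensitivity of time-compensated sun-compass headings
#'
#' Adds to the fixed-sun term the clock-shift term from the longitude
#' displacement, \eqn{-R_{step}\cos\alpha_{i-1}\sin\phi_{s_{ref}}/\cos\phi_{i-1}}
#' (always negative, hence self-correcting, for Southward components), and
#' for the `"proximate"` variant the (small, likewise negative) term from
#' the rate latitude moving with the migrant,
#' \eqn{(\lambda_i - \lambda_{ref})\,R_{step}\sin\alpha_{i-1}\cos\phi_i}.
#'
#' @inheritParams sensitivity_fixed_sun
#' @param variant `"classic"` or `"proximate"`.
#' @param sref_lat_deg latitude defining the time-compensation rate
#'   (classic variant; default the pre-step latitude).
#' @param dlam_ref_deg longitudinal displacement since the clock-reset site
#'   (degrees; proximate variant; default the single-step displacement).
#' @return signed derivative; negative values are self-correcting.
#' @export
sensitivity_tcsc <- function(alpha_prev_deg, lat_deg, day, r_step_km = 360,
                             variant = c("classic", "proximate"),
                             sref_lat_deg = lat_deg, dlam_ref_deg = NULL) {
  variant <- match.arg(variant)
  r <- r_step_km / R_EARTH
  a <- .rad(alpha_prev_deg); p <- .rad(lat_deg)
  pi_ <- p - r * cos(a)
  d <- .rad(solar_declination(day))
  fs <- r * sin(a) * .dtheta_dphi(pi_, d)
  if (variant == "classic") {
    fs - r * cos(a) * sin(.rad(sref_lat_deg)) / cos(p)
  } else {
    dlam <- if (is.null(dlam_ref_deg)) -.deg(r * sin(a) / cos(p)) else dlam_ref_deg
    fs - r * cos(a) * sin(pi_) / cos(p) + .rad(dlam) * r * sin(a) * cos(pi_)
  }
}

#' Finite-difference sensitivity oracle
#'
#' Central finite difference of the composed map: perturb the previous
#' heading, advance one planar flight-step, and re-evaluate the course's
#' expected heading at the post-step location. Serves as the independent
#' check of the analytic sensitivity expressions.
#'
#' @inheritParams sensitivity_tcsc
#' @param course one of `"geographic_lox"`, `"magnetoclinic"`,
#'   `"fixed_sun"`, `"tcsc"`.
#' @param alpha0_deg,lat0_deg magnetoclinic imprint (defaults to local state).
#' @param h perturbation in radians (default 1e-5).
#' @return numerical derivative (dimensionless).
#' @export
sensitivity_fd <- function(course, alpha_prev_deg, lat_deg, day = 244,
                           r_step_km = 360,
                           alpha0_deg = alpha_prev_deg, lat0_deg = lat_deg,
                           variant = c("classic", "proximate"),
                           sref_lat_deg = lat_deg, h = 1e-5) {
  course <- match.arg(course, c("geographic_lox", "geomagnetic_lox",
                                "magnetoclinic", "fixed_sun", "tcsc"))
  variant <- match.arg(variant)
  r <- r_step_km / R_EARTH
  p <- .rad(lat_deg); lam0 <- 0
  d <- .rad(solar_declination(day))
  f <- switch(course,
    geographic_lox = , geomagnetic_lox = function(a) .rad(alpha0_deg),
    magnetoclinic = function(a) {
      s <- .step_rad(p, lam0, a, r)
      asin(sin(.rad(alpha0_deg)) * tan(s$phi) / tan(.rad(lat0_deg)))
    },
    fixed_sun = function(a) {
      s <- .step_rad(p, lam0, a, r)
      .theta_s_rad(s$phi, d) # the constant sun offset drops out
    },
    tcsc = function(a) {
      s <- .step_rad(p, lam0, a, r)
      srp <- if (variant == "proximate") s$phi else .rad(sref_lat_deg)
      .theta_s_rad(s$phi, d) + (s$lam - lam0) * sin(srp)
    }
  )
  a <- .rad(alpha_prev_deg)
  (f(a + h) - f(a - h)) / (2 * h)
}

#' Latitude-by-heading sensitivity grid
#'
#' Evaluates a course's sensitivity over a grid of pre-step latitudes and
#' headings (the layout of the published-style heat maps). Cells where the
#' course rule is undefined -- no twilight at polar latitudes and dates, or
#' magnetoclinic East/West fallback states -- are `NA`-masked. Sensitivity
#' is reported both as the raw derivative and as percentage error growth
#' per step (derivative x 100).
#'
#' @param course course type (see [sensitivity_fd()]).
#' @param day day of year (sun courses).
#' @param lats,headings grid vectors in degrees.
#' @param r_step_km flight-step distance in km (default 360).
#' @param variant TCSC variant.
#' @return object of class `sensitivity_grid` with fields `latitudes`,
#'   `headings`, `derivative` (matrix, lat x heading), `percent`, `course`,
#'   `day`.
#' @export
sensitivity_grid <- function(course, day = 213,
                             lats = seq(0, 80, by = 5),
                             headings = seq(-85, 85, by = 5),
                             r_step_km = 360,
                             variant = c("classic", "proximate")) {
  course <- match.arg(course, c("geographic_lox", "geomagnetic_lox",
                                "magnetoclinic", "fixed_sun", "tcsc"))
  variant <- match.arg(variant)
  m <- matrix(NA_real_, length(lats), length(headings),
              dimnames = list(lat = lats, heading = headings))
  for (j in seq_along(headings)) {
    a <- headings[j]
    m[, j] <- switch(course,
      geographic_lox = , geomagnetic_lox = 0,
      magnetoclinic = sensitivity_magnetoclinic(a, lats, r_step_km),
      fixed_sun = sensitivity_fixed_sun(a, lats, day, r_step_km),
      tcsc = sensitivity_tcsc(a, lats, day, r_step_km, variant)
    )
  }
  structure(list(latitudes = lats, headings = headings,
                 derivative = m, percent = 100 * m,
                 course = course, day = day, variant = variant),
            class = "sensitivity_grid")
}

#' @export
as.data.frame.sensitivity_grid <- function(x, ...) {
  data.frame(
    lat = rep(x$latitudes, times = length(x$headings)),
    heading = rep(x$headings, each = length(x$latitudes)),
    value = as.vector(x$percent)
  )
}

#' Export a sensitivity grid as a delimited table
#'
#' Writes (lat, heading, value-percent) rows for external plotting.
#'
#' @param x a `sensitivity_grid`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_sensitivity_grid <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  v <- x$percent[is.finite(x$percent)]
  cat(sprintf("<sensitivity_grid> %s (day %d): %d x %d cells, %.1f%% masked\n",
              x$course, x$day, length(x$latitudes), length(x$headings),
              100 * mean(!is.finite(x$percent))))
  if (length(v)) cat(sprintf("  percent growth range [%.2f, %.2f]\n", min(v), max(v)))
  invisible(x)
}
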