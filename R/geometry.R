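# Spherical positions, stepwise planar movement, great-circle utilities and
# route-level spherical-geometry factors.

#' Mean Earth radius (km) used throughout the package
#' @export
R_EARTH <- 6371

#' Convert between internal headings and compass bearings
#'
#' Headings `alpha` are measured clockwise from geographic South for
#' Northern-Hemisphere departures (so `alpha = 0` is due South, positive is
#' westward), and counter-clockwise from North for Southern-Hemisphere
#' departures. This matches the convention in which equatorward migration
#' has small `alpha`. Conventional compass bearings are clockwise from
#' North.
#'
#' @param alpha_deg internal heading in degrees.
#' @param bearing_deg compass bearing in degrees clockwise from North.
#' @param hemisphere `"N"` or `"S"` (hemisphere of departure).
#' @return the converted angle in degrees; bearings in [0, 360), headings
#'   wrapped to (-180, 180].
#' @examples
#' alpha_to_bearing(39)   # 219: the SW bearing of a heading 39 deg W of S
#' bearing_to_alpha(108)  # -72: ESE as a heading E of S
#' @export
alpha_to_bearing <- function(alpha_deg, hemisphere = "N") {
  if (hemisphere == "N") (180 + alpha_deg) %% 360 else (-alpha_deg) %% 360
}

#' @rdname alpha_to_bearing
#' @export
bearing_to_alpha <- function(bearing_deg, hemisphere = "N") {
  a <- if (hemisphere == "N") bearing_deg - 180 else -bearing_deg
  .deg(.wrap_pi(.rad(a)))
}

# internal, radians: one planar step. phi' = phi - r cos a; lam' = lam - r sin a / cos phi
.step_rad <- function(phi, lam, alpha, r) {
  phi2 <- phi - r * cos(alpha)
  lam2 <- .wrap_pi(lam - r * sin(alpha) / cos(phi))
  list(phi = phi2, lam = lam2)
}

#' Advance a position by one planar flight-step
#'
#' Stepwise planar approximation of movement on the sphere: latitude
#' decreases by the along-meridian component and the longitude change is
#' magnified by \eqn{1/\cos\phi} (meridian convergence). Sub-stepping (e.g.
#' hourly) improves the approximation; the simulator uses hourly substeps.
#'
#' @param lat_deg,lon_deg current position in degrees.
#' @param alpha_deg heading in degrees, clockwise from geographic South
#'   (positive = westward component).
#' @param r_step_km step length in km (> 0).
#' @return named numeric vector `c(lat, lon)` in degrees.
#' @export
step_position <- function(lat_deg, lon_deg, alpha_deg, r_step_km) {
  if (any(r_step_km <= 0)) stop("`r_step_km` must be > 0")
  s <- .step_rad(.rad(unname(lat_deg)), .rad(unname(lon_deg)),
                 .rad(unname(alpha_deg)), r_step_km / R_EARTH)
  if (any(abs(s$phi) >= pi / 2)) {
    stop("flight-step crosses a pole; outside the model's domain")
  }
  c(lat = .deg(s$phi), lon = .deg(s$lam))
}

#' Great-circle distance and bearings between two points
#'
#' Spherical distance and initial/final bearings with the package Earth
#' radius ([R_EARTH]); thin wrapper over \pkg{geosphere}.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return list with `distance_km`, `bearing_initial` and `bearing_final`
#'   (degrees clockwise from North).
#' @export
great_circle <- function(lat1, lon1, lat2, lon2) {
  if (isTRUE(all.equal(c(lat1, lon1), c(lat2, lon2)))) stop("points must be distinct")
  if (isTRUE(all.equal(lat1, -lat2)) &&
      isTRUE(all.equal(abs(.wrap_pi(.rad(lon1 - lon2))), pi))) {
    stop("antipodal points: bearings undefined")
  }
  p1 <- c(lon1, lat1)
  p2 <- c(lon2, lat2)
  list(
    distance_km = geosphere::distHaversine(p1, p2, r = R_EARTH),
    bearing_initial = geosphere::bearing(p1, p2) %% 360,
    bearing_final = geosphere::finalBearing(p1, p2) %% 360
  )
}

#' Loxodrome (rhumb-line) bearing and distance
#'
#' Constant-bearing course between two points, from the Mercator-projected
#' latitude difference.
#'
#' @inheritParams great_circle
#' @return list with `distance_km` and `bearing` (degrees from North).
#' @export
loxodrome <- function(lat1, lon1, lat2, lon2) {
  phi1 <- .rad(lat1); phi2 <- .rad(lat2)
  dpsi <- log(tan(phi2 / 2 + pi / 4)) - log(tan(phi1 / 2 + pi / 4))
  dlam <- .wrap_pi(.rad(lon2 - lon1))
  brg <- atan2(dlam, dpsi) %% (2 * pi)
  dphi <- phi2 - phi1
  dist <- if (abs(dphi) > 1e-12) {
    abs(dphi / cos(brg)) * R_EARTH
  } else {
    abs(dlam) * cos(phi1) * R_EARTH
  }
  list(distance_km = dist, bearing = .deg(brg))
}

#' Mercator (latitude-averaged secant) factor of a route
#'
#' The factor by which longitudinal errors are magnified when aggregated
#' over a route from latitude `lat0_deg` to `latA_deg`:
#' \deqn{L = \frac{1}{\phi_0 - \phi_A}\,
#'   \ln\!\frac{\tan(\phi_0/2 + \pi/4)}{\tan(\phi_A/2 + \pi/4)},}
#' the mean of \eqn{\sec\phi} over the latitude band (as in a Mercator
#' projection). Continuous limit `sec(lat0)` is returned for equal
#' latitudes.
#'
#' @param lat0_deg,latA_deg initial (natal) and arrival latitudes in degrees,
#'   both within (-90, 90).
#' @return dimensionless factor L >= 1 for bands containing the equatorward
#'   latitude of smaller secant.
#' @examples
#' mercator_factor(65, 0) # ~ 1.328
#' @export
mercator_factor <- function(lat0_deg, latA_deg) {
  if (any(abs(c(lat0_deg, latA_deg)) >= 90)) stop("latitudes must be within (-90, 90)")
  p0 <- .rad(lat0_deg); pA <- .rad(latA_deg)
  if (abs(p0 - pA) < 1e-9) return(1 / cos(p0))
  (log(tan(p0 / 2 + pi / 4)) - log(tan(pA / 2 + pi / 4))) / (p0 - pA)
}

#' Spherical-geometry factor of a route
#'
#' Modulates the Mercator factor `L` by the route-mean heading:
#' \deqn{G = \sqrt{(L \sin\bar\alpha)^2 + \cos^2\bar\alpha},}
#' so that G = 1 for North-South routes (no longitude bands crossed) and
#' G = L for purely East-West routes.
#'
#' @param L Mercator factor (>= 1), see [mercator_factor()].
#' @param mean_heading_deg route-mean heading in degrees clockwise from South.
#' @return G in [1, L].
#' @export
geometry_factor <- function(L, mean_heading_deg) {
  if (any(L < 1)) stop("`L` must be >= 1")
  a <- .rad(mean_heading_deg)
  sqrt((L * sin(a))^2 + cos(a)^2)
}

#' Goal breadths of a migration route
#'
#' Three route-level angular breadths of the goal area:
#' \eqn{\beta = \arctan(R_{goal}/R_{mig})} (small-angle equivalent
#' \eqn{R_{goal}/R_{mig}}), the length-adjusted breadth
#' \eqn{\beta_{adj} = \sqrt{N_0}\,R_{goal}/R_{mig}} (the route-level
#' predictor of arrival probability under many-wrongs averaging), and the
#' arrival-latitude-adjusted breadth
#' \deqn{\beta_A = \beta\sqrt{\sin^2\bar\alpha +
#'   (\cos\bar\alpha/\cos\phi_A)^2}}
#' accounting for a geographically circular goal on the sphere.
#'
#' @param N0 error-free (minimum) number of flight-steps (>= 1).
#' @param R_goal_km goal radius in km.
#' @param R_mig_km migration distance in km (> `R_goal_km`).
#' @param mean_heading_deg route-mean heading, degrees clockwise from South.
#' @param lat_arrival_deg arrival latitude in degrees.
#' @return list with `beta`, `beta_adj`, `beta_A` (radians).
#' @examples
#' goal_breadths(36.9, 100, 3290)$beta_adj # ~ 0.18 (monarch butterfly)
#' @export
goal_breadths <- function(N0, R_goal_km, R_mig_km,
                          mean_heading_deg = 0, lat_arrival_deg = 0) {
  if (R_mig_km <= R_goal_km || R_goal_km <= 0) stop("need R_mig > R_goal > 0")
  if (N0 < 1) stop("`N0` must be >= 1")
  beta <- atan(R_goal_km / R_mig_km)
  a <- .rad(mean_heading_deg)
  list(
    beta = beta,
    beta_adj = sqrt(N0) * R_goal_km / R_mig_km,
    beta_A = beta * sqrt(sin(a)^2 + (cos(a) / cos(.rad(lat_arrival_deg)))^2)
  )
}

#' Route geometry summary
#'
#' Bundles the great-circle and loxodrome solutions between natal and goal
#' locations with the Mercator factor, spherical-geometry factors and goal
#' breadths. The route-mean heading used for G is the average of the
#' initial and final great-circle bearings (appropriate for
#' direction-shifting sun-compass courses); the constant loxodrome bearing
#' is also reported for loxodrome courses.
#'
#' @param natal_lat,natal_lon,goal_lat,goal_lon coordinates in degrees.
#' @param goal_radius_km goal radius (km).
#' @param N0 error-free number of flight-steps (used for `beta_adj`; may be
#'   `NULL` to derive from `r_step_km`).
#' @param r_step_km flight-step distance (km), used to derive `N0` when not
#'   given.
#' @param hemisphere hemisphere of departure, `"N"` or `"S"`.
#' @return object of class `route_geometry`: a list with distances,
#'   bearings, internal headings, `L`, `G_gc`, `G_lox`, and the goal
#'   breadths.
#' @export
route_geometry <- function(natal_lat, natal_lon, goal_lat, goal_lon,
                           goal_radius_km, N0 = NULL, r_step_km = NULL,
                           hemisphere = "N") {
  gc <- great_circle(natal_lat, natal_lon, goal_lat, goal_lon)
  lox <- loxodrome(natal_lat, natal_lon, goal_lat, goal_lon)
  if (is.null(N0)) {
    if (is.null(r_step_km)) stop("supply `N0` or `r_step_km`")
    N0 <- gc$distance_km / r_step_km
  }
  a_init <- bearing_to_alpha(gc$bearing_initial, hemisphere)
  a_fin <- bearing_to_alpha(gc$bearing_final, hemisphere)
  a_mean <- .deg(.wrap_pi(.rad(a_init) + .wrap_pi(.rad(a_fin - a_init)) / 2))
  a_lox <- bearing_to_alpha(lox$bearing, hemisphere)
  L <- mercator_factor(natal_lat, goal_lat)
  br <- goal_breadths(N0, goal_radius_km, gc$distance_km, a_mean, goal_lat)
  structure(list(
    natal = c(lat = natal_lat, lon = natal_lon),
    goal = c(lat = goal_lat, lon = goal_lon),
    goal_radius_km = goal_radius_km,
    distance_gc_km = gc$distance_km,
    distance_lox_km = lox$distance_km,
    bearing_initial = gc$bearing_initial,
    bearing_final = gc$bearing_final,
    bearing_lox = lox$bearing,
    alpha_initial = a_init, alpha_final = a_fin,
    alpha_mean = a_mean, alpha_lox = a_lox,
    N0 = N0, L = L,
    G_gc = geometry_factor(L, a_mean),
    G_lox = geometry_factor(L, a_lox),
    beta = br$beta, beta_adj = br$beta_adj, beta_A = br$beta_A,
    hemisphere = hemisphere
  ), class = "route_geometry")
}

#' @export
print.route_geometry <- function(x, ...) {
  cat(sprintf(
    "Route %.1f,%.1f -> %.1f,%.1f  gc %.0f km (bearing %.0f->%.0f)\n",
    x$natal[1], x$natal[2], x$goal[1], x$goal[2],
    x$distance_gc_km, x$bearing_initial, x$bearing_final
  ))
  cat(sprintf("  N0 %.1f  L %.3f  G(gc) %.3f  G(lox) %.3f\n",
              x$N0, x$L, x$G_gc, x$G_lox))
  cat(sprintf("  beta %.3f  beta_adj %.2f  beta_A %.3f\n",
              x$beta, x$beta_adj, x$beta_A))
  invisible(x)
}
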