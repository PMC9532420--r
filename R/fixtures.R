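# Packaged parameter sets: nine migratory species, generic-migrant
# defaults and deterministic synthetic scenarios for tests.

#' The packaged species parameter table
#'
#' Route and schedule parameters for nine airborne migrant populations
#' (seven night-migratory birds, the Nathusius bat and the day-migrating
#' monarch butterfly): goal radius, departure-date distribution and latest
#' arrival, great-circle and loxodrome distances and initial bearings,
#' flight speed, flight-step distance, bout structure and stopover
#' durations, minimum (error-free) and maximum flight-step counts, and
#' length-adjusted goal breadth. The natal/goal coordinates are
#' representative points chosen for the named regions (the sources give
#' regions, not coordinates) and are marked `synthetic` in the
#' `coords_canonical` column: species simulations are therefore
#' approximations of the studied routes, while all printed quantities
#' (distances, headings, step counts, breadths) are stored verbatim.
#'
#' @return data frame, one row per species.
#' @export
species_table <- function() {
  utils::read.csv(system.file("extdata", "species_params.csv",
                              package = "compasscourse"),
                  stringsAsFactors = FALSE)
}

#' Load a species parameter set
#'
#' @param name species identifier (see [species_table()]`$name`).
#' @return list of class `species_params` with the fixture row plus the
#'   derived flight hours per step (`flight_hours`), a [schedule()], and a
#'   [route_geometry()] built from the representative coordinates with the
#'   stored `n_min`.
#' @examples
#' sp <- load_species("monarch")
#' sp$goal_radius_km # 100
#' @export
load_species <- function(name) {
  tab <- species_table()
  if (!name %in% tab$name) {
    stop("unknown species '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  }
  row <- as.list(tab[tab$name == name, ])
  row$flight_hours <- max(1L, round(row$step_km * 1000 /
                                      (row$flight_speed_ms * 3600)))
  row$schedule <- schedule(
    flights_per_bout = row$consecutive_steps,
    stopover_mean = row$stopover_mean_d, stopover_sd = row$stopover_sd_d,
    flight_hours = row$flight_hours,
    depart_mean = row$depart_day, depart_sd = row$depart_sd,
    max_steps = row$n_max, max_arrival_day = row$max_arrival_day
  )
  row$route <- route_geometry(row$natal_lat, row$natal_lon,
                              row$goal_lat, row$goal_lon,
                              row$goal_radius_km, N0 = row$n_min)
  structure(row, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s (%s): %d km goal, %.0f km gc, %d-h steps\n",
              x$name, x$common_name, x$goal_radius_km, x$distance_gc_km,
              x$flight_hours))
  invisible(x)
}

#' Route table for performance fitting
#'
#' Per-species route geometry predictors for [fit_performance()]:
#' arrival-adjusted goal breadth, spherical-geometry factor (great-circle
#' mean heading for sun courses, loxodrome heading otherwise), step
#' counts, and flight-step distance scaled by the species median.
#'
#' @param course_type course whose route-mean heading convention is used.
#' @return data frame with columns `species`, `beta_A`, `G`, `N0`,
#'   `N_max`, `mean_heading_deg`, `r_step_scaled`.
#' @export
species_route_table <- function(course_type = "geographic_lox") {
  tab <- species_table()
  rows <- lapply(tab$name, function(nm) {
    sp <- load_species(nm)
    rg <- sp$route
    use_gc <- course_type %in% c("tcsc", "fixed_sun")
    data.frame(
      species = nm,
      beta_A = rg$beta_A,
      G = if (use_gc) rg$G_gc else rg$G_lox,
      N0 = sp$n_min, N_max = sp$n_max,
      mean_heading_deg = if (use_gc) rg$alpha_mean else rg$alpha_lox,
      r_step_km = sp$step_km
    )
  })
  out <- do.call(rbind, rows)
  out$r_step_scaled <- out$r_step_km / stats::median(out$r_step_km)
  out
}

#' Deterministic synthetic scenarios for tests
#'
#' Small, fully specified run configurations in a dipole field:
#' `"due_south"` (45N to 25N along a meridian, G = 1), `"east_west"` (a
#' strongly zonal route at high latitude, L > 1) and `"high_latitude"`
#' (the 65N-to-equator generic route). Identical inputs yield identical
#' configurations.
#'
#' @param kind scenario name.
#' @param sigma_step_deg lumped per-step deviation (deg; `NULL` for
#'   error-free).
#' @param n number of individuals.
#' @return list with `route`, `prec`, `sched`, `n` ready for
#'   [run_population()].
#' @export
make_scenario <- function(kind = c("due_south", "east_west", "high_latitude"),
                          sigma_step_deg = NULL, n = 2000) {
  kind <- match.arg(kind)
  route <- switch(kind,
    due_south = list(natal_lat = 45, natal_lon = 0, goal_lat = 25,
                     goal_lon = 0, goal_radius_km = 500),
    east_west = list(natal_lat = 60, natal_lon = 0, goal_lat = 50,
                     goal_lon = -40, goal_radius_km = 500),
    high_latitude = list(natal_lat = 65, natal_lon = 0, goal_lat = 0,
                         goal_lon = 0, goal_radius_km = 500)
  )
  prec <- if (is.null(sigma_step_deg)) {
    precision_spec(individual = 0)
  } else {
    precision_spec(individual = 0, step = sigma_step_deg)
  }
  list(route = route, prec = prec,
       sched = schedule(max_steps = if (kind == "high_latitude") 60 else 40),
       n = n, kind = kind)
}
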