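# Shared helpers for the test suite.

# degrees <-> radians (mirror the package internals without reaching in)
rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi

# the generic due-South test route (45N -> 25N along a meridian, G = 1)
due_south_route <- function() {
  list(natal_lat = 45, natal_lon = 0, goal_lat = 25, goal_lon = 0,
       goal_radius_km = 500)
}

# error-free step count with in-flight goal detection: the goal is reached
# once within its radius, i.e. after ceiling((R_mig - R_goal)/R_step) steps
error_free_steps <- function(route, r_step_km = 360) {
  d <- great_circle(route$natal_lat, route$natal_lon,
                    route$goal_lat, route$goal_lon)$distance_km
  ceiling((d - route$goal_radius_km) / r_step_km)
}
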