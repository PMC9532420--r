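# The stochastic population migration engine: hourly flight substeps with
# biologically structured orientation errors, flight/stopover schedules,
# in-flight goal detection, termination rules, and route-optimal
# initial-heading search. All per-individual state is carried in vectors
# and flight-steps are advanced in lock-step for speed.

#' Orientation-error magnitudes
#'
#' All magnitudes are angular deviations in degrees; 0 is the exact,
#' deterministic limit. Mechanistic mode combines cue-detection, (optional)
#' cue-transfer, in-flight cue-maintenance, within-flight drift and
#' between-individual variability in the inherited heading. Alternatively
#' a single lumped per-step deviation (`step`) replaces the within-step
#' components (all sources implicit); the two modes are mutually exclusive.
#'
#' @param detect cue-detection deviation on departure (deg).
#' @param transfer cue-transfer deviation (deg; only drawn for
#'   cue-transferred courses).
#' @param maintain in-flight (hourly) cue-maintenance deviation (deg).
#' @param drift target within-flight drift deviation per flight-step (deg),
#'   realized as a lag-1 autocorrelated hourly process.
#' @param individual between-individual deviation of inherited headings
#'   (deg; default 2.5).
#' @param step lumped per-flight-step deviation (deg) or `NULL` for
#'   mechanistic mode.
#' @param drift_autocorr lag-1 autocorrelation of the hourly drift process.
#' @return list of class `precision_spec`.
#' @export
precision_spec <- function(detect = 0, transfer = 0, maintain = 0, drift = 0,
                           individual = 2.5, step = NULL,
                           drift_autocorr = 0.5) {
  vals <- c(detect, transfer, maintain, drift, individual, step)
  if (any(vals < 0)) stop("error magnitudes must be >= 0")
  if (!is.null(step) && any(c(detect, transfer, maintain, drift) > 0)) {
    stop("lumped `step` mode and mechanistic components are mutually exclusive")
  }
  structure(list(detect = detect, transfer = transfer, maintain = maintain,
                 drift = drift, individual = individual, step = step,
                 drift_autocorr = drift_autocorr),
            class = "precision_spec")
}

#' Migration schedule
#'
#' Bouts of consecutive nightly (or daily) flight-steps separated by
#' extended stopovers, with a normally distributed departure date (rounded
#' to day; out-of-range draws are redrawn) and seasonal limits. Defaults
#' are the generic-migrant values: departure September 15 +/- 5 days,
#' 8-hour flight-steps, bouts of 5 steps, stopovers of 5 +/- 2 days.
#'
#' @param flights_per_bout consecutive flight-steps between stopovers.
#' @param stopover_mean,stopover_sd stopover duration, days (truncated >= 1).
#' @param flight_hours hours flown per flight-step (n_H).
#' @param depart_mean,depart_sd departure day-of-year distribution.
#' @param max_steps maximum number of flight-steps (N_max).
#' @param max_arrival_day latest day (may exceed 365 for journeys crossing
#'   New Year) on which arrival still counts.
#' @return list of class `migration_schedule`.
#' @export
schedule <- function(flights_per_bout = 5, stopover_mean = 5, stopover_sd = 2,
                     flight_hours = 8, depart_mean = 258, depart_sd = 5,
                     max_steps = 60, max_arrival_day = 365) {
  stopifnot(flights_per_bout >= 1, flight_hours >= 1, max_steps >= 1,
            stopover_mean >= 0, stopover_sd >= 0, depart_sd >= 0)
  structure(list(flights_per_bout = flights_per_bout,
                 stopover_mean = stopover_mean, stopover_sd = stopover_sd,
                 flight_hours = flight_hours,
                 depart_mean = depart_mean, depart_sd = depart_sd,
                 max_steps = max_steps, max_arrival_day = max_arrival_day),
            class = "migration_schedule")
}

# ---- drift calibration -----------------------------------------------------

.drift_cache <- new.env(parent = emptyenv())

#' Calibrate the hourly drift process
#'
#' Finds the stationary standard deviation of the lag-1 autocorrelated
#' hourly heading-drift process such that the angular deviation of the net
#' flight-step direction attributable to drift equals `sigma_target_deg`.
#' Calibration is by Monte-Carlo (flights of `n_H` unit hourly moves whose
#' headings are the drift process alone), iterated once on the measured
#' deviation, and cached per (target, n_H, autocorrelation).
#'
#' @param sigma_target_deg target per-flight-step drift deviation (deg).
#' @param n_H flight hours per step.
#' @param autocorr lag-1 autocorrelation coefficient.
#' @param n_mc Monte-Carlo flights per calibration pass.
#' @return list with `hourly_sd` (stationary sd, deg), `innovation_sd`
#'   (deg) and `realized` (the Monte-Carlo check of the per-step
#'   deviation, deg).
#' @export
calibrate_drift <- function(sigma_target_deg, n_H, autocorr = 0.5,
                            n_mc = 40000) {
  if (sigma_target_deg < 0) stop("`sigma_target_deg` must be >= 0")
  if (sigma_target_deg == 0) {
    return(list(hourly_sd = 0, innovation_sd = 0, realized = 0))
  }
  key <- sprintf("%.6g|%d|%.4g", sigma_target_deg, n_H, autocorr)
  if (!is.null(.drift_cache[[key]])) return(.drift_cache[[key]])

  measure <- function(sd_deg) {
    d <- .ar1_matrix(n_mc, n_H, .rad(sd_deg), autocorr)
    dirs <- atan2(rowSums(sin(d)), rowSums(cos(d)))
    .deg(stats::sd(dirs))
  }
  # deviation is ~linear in scale in the small-angle regime: one linear
  # guess from a probe, then one corrective iteration
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(20201L)
  probe <- 5
  dev0 <- measure(probe)
  sd1 <- probe * sigma_target_deg / dev0
  dev1 <- measure(sd1)
  sd2 <- sd1 * sigma_target_deg / dev1
  dev2 <- measure(sd2)
  out <- list(hourly_sd = sd2,
              innovation_sd = sd2 * sqrt(1 - autocorr^2),
              realized = dev2)
  .drift_cache[[key]] <- out
  out
}

# n x h matrix of a stationary AR(1) process with stationary sd `s` (rad)
.ar1_matrix <- function(n, h, s, rho) {
  d <- matrix(0, n, h)
  d[, 1] <- stats::rnorm(n, 0, s)
  if (h > 1) {
    inn <- s * sqrt(1 - rho^2)
    for (k in 2:h) d[, k] <- rho * d[, k - 1] + stats::rnorm(n, 0, inn)
  }
  d
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# ---- single flight-step (vectorized over individuals) ----------------------

# Execute one flight-step for `m` individuals in parallel.
# Arguments (all length m unless noted): phi, lam (rad), mu (expected
# departure heading, rad), day; spec: course_spec-like list; prec:
# precision_spec; k_mag: magnetoclinic imprint sin(a0)/tan(phi_m0) per
# individual (or NULL); alpha0i: per-individual inherited heading (rad).
# Returns list with final phi/lam, net direction (rad), and the hourly
# position matrices (m x (nH+1)) for in-flight goal checks.
.fly_step_core <- function(phi, lam, mu, day, spec, prec, n_H, r_hour,
                           k_mag = NULL, alpha0i = NULL, drift_sd_rad = 0,
                           drift_rho = 0.5) {
  m <- length(phi)
  PHI <- matrix(NA_real_, m, n_H + 1)
  LAM <- matrix(NA_real_, m, n_H + 1)
  PHI[, 1] <- phi; LAM[, 1] <- lam
  lumped <- !is.null(prec$step)

  if (lumped) {
    eps <- .rvm_rad(m, 0, .kappa_of(prec$step))
  } else {
    detect <- .rvm_rad(m, 0, .kappa_of(prec$detect))
    bias <- if (spec$transferred) {
      detect + .rvm_rad(m, 0, .kappa_of(prec$transfer))
    } else NULL
  }
  d <- if (drift_sd_rad > 0) stats::rnorm(m, 0, drift_sd_rad) else numeric(m)
  inn <- drift_sd_rad * sqrt(1 - drift_rho^2)
  hourly_update <- !spec$transferred &&
    spec$course %in% c("geomagnetic_lox", "magnetoclinic")
  fallback <- rep(FALSE, m)

  p <- phi; l <- lam
  for (h in seq_len(n_H)) {
    if (h > 1 && drift_sd_rad > 0) d <- drift_rho * d + stats::rnorm(m, 0, inn)
    mu_h <- mu
    if (hourly_update) {
      if (spec$course == "geomagnetic_lox") {
        decl <- .rad(spec$provider(.deg(p), .deg(l), day)$declination)
        mu_h <- alpha0i + decl
      } else { # magnetoclinic, dipole frame: re-solve at current latitude
        mc <- .magnetoclinic_rad_k(k_mag, p)
        mu_h <- mc$alpha
        fallback <- mc$fallback
      }
    }
    realized <- if (lumped) {
      mu_h + eps
    } else if (spec$transferred) {
      mu_h + bias + .rvm_rad(m, 0, .kappa_of(prec$maintain)) + d
    } else {
      maint <- if (h == 1) detect else .rvm_rad(m, 0, .kappa_of(prec$maintain))
      mu_h + maint + d
    }
    s <- .step_rad(p, l, realized, r_hour)
    p <- pmin(pi / 2 - 1e-9, pmax(-pi / 2 + 1e-9, s$phi))
    l <- s$lam
    PHI[, h + 1] <- p; LAM[, h + 1] <- l
  }
  net_dir <- atan2(-cos(phi) * .wrap_pi(l - lam), phi - p) # heading from S, W+
  list(phi = p, lam = l, dir = net_dir, PHI = PHI, LAM = LAM,
       fallback = fallback)
}

# magnetoclinic via the preserved constant k = sin(a0)/tan(phi_m0)
.magnetoclinic_rad_k <- function(k, phi_m) {
  arg <- k * tan(phi_m)
  fb <- abs(arg) > 1
  list(alpha = ifelse(fb, sign(k) * pi / 2, asin(pmin(1, pmax(-1, arg)))),
       fallback = fb)
}

#' Execute one flight-step
#'
#' Runs a single flight-step of `n_H` hourly substeps for one or more
#' individuals sharing the same course and error structure, composing the
#' per-step error mechanics: a cue-detection error drawn once; for
#' cue-transferred courses a one-off transfer error that fixes the biased
#' reference for the flight (hourly maintenance re-centres on it); for
#' non-transferred courses hourly maintenance re-determined from the true
#' expected heading (errors average out across hours); and an hourly
#' lag-1-autocorrelated drift increment. Positions advance by the planar
#' step equations at `r_step/n_H` per hour.
#'
#' @param spec a [course_spec()].
#' @param lat_deg,lon_deg starting positions (degrees; vectorized).
#' @param day day of year.
#' @param prec a [precision_spec()].
#' @param n_H flight hours.
#' @param flight_speed_ms flight speed (m/s); step length is
#'   `3.6 * speed * n_H / R_EARTH` radians.
#' @param clock optional [clock_state()] for TCSC courses.
#' @return list with `lat`, `lon` (degrees), `direction_deg` (net
#'   flight-step direction, degrees from South) and `expected_deg` (the
#'   error-free heading).
#' @export
fly_step <- function(spec, lat_deg, lon_deg = 0, day = spec$depart_day,
                     prec = precision_spec(), n_H = 8,
                     flight_speed_ms = 12.5, clock = NULL) {
  m <- max(length(lat_deg), length(lon_deg))
  lat_deg <- rep_len(lat_deg, m); lon_deg <- rep_len(lon_deg, m)
  r_step <- 3.6 * flight_speed_ms * n_H / R_EARTH
  alpha0i <- rep_len(.rad(spec$alpha0), m)
  k_mag <- NULL
  mu <- switch(spec$course,
    geographic_lox = alpha0i,
    geomagnetic_lox = alpha0i +
      .rad(spec$provider(lat_deg, lon_deg, day)$declination),
    magnetoclinic = {
      k_mag <- sin(alpha0i) / tan(.rad(spec$phi_m0))
      .magnetoclinic_rad_k(k_mag, .rad(lat_deg))$alpha
    },
    fixed_sun = .rad(heading_fixed_sun(spec, lat_deg, day)),
    tcsc = {
      if (is.null(clock)) {
        clock <- clock_state(spec$alpha0, spec$theta_s0, spec$natal_lon,
                             spec$natal_lat)
      }
      .rad(heading_tcsc(spec, clock, lat_deg, lon_deg, day))
    }
  )
  dr <- if (is.null(prec$step) && prec$drift > 0) {
    calibrate_drift(prec$drift, n_H, prec$drift_autocorr)
  } else list(hourly_sd = 0)
  out <- .fly_step_core(.rad(lat_deg), .rad(lon_deg), mu, day, spec, prec,
                        n_H, r_step / n_H, k_mag = k_mag, alpha0i = alpha0i,
                        drift_sd_rad = .rad(dr$hourly_sd),
                        drift_rho = prec$drift_autocorr)
  list(lat = .deg(out$phi), lon = .deg(out$lam),
       direction_deg = .deg(out$dir), expected_deg = .deg(mu))
}

# ---- population simulation -------------------------------------------------

# great-circle distance (rad angle) between point vectors, haversine
.gc_rad <- function(phi1, lam1, phi2, lam2) {
  dphi <- phi2 - phi1
  dlam <- lam2 - lam1
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * asin(pmin(1, sqrt(a)))
}

#' Simulate a migratory population
#'
#' Simulates `n` individuals following a compass course from natal grounds
#' toward a goal area, with the full error mechanics of [fly_step()], a
#' bout/stopover schedule, in-flight goal detection checked once per decile
#' of each flight-step's duration, and the termination rules: arrival
#' within the goal radius (by the latest arrival day), overshoot (1000 km
#' South of the goal latitude), or exhaustion of the step or date budget.
#' TCSC clock bookkeeping follows the course variant: at departure from an
#' extended stopover the classic and proximate variants retain the realized
#' direction of the previous flight-step as the new reference heading and
#' reset the clock references; the retain-first-night variant freezes the
#' TCSC heading evaluated on the first stopover night instead.
#'
#' @param route list with `natal_lat`, `natal_lon`, `goal_lat`, `goal_lon`
#'   (degrees) and `goal_radius_km`, or a [route_geometry()].
#' @param course course type (see [course_spec()]).
#' @param alpha0 inherited initial heading (degrees from South).
#' @param prec a [precision_spec()].
#' @param sched a [schedule()].
#' @param n number of individuals.
#' @param flight_speed_ms flight (air) speed, m/s.
#' @param seed integer seed for reproducibility (same seed, same result).
#' @param tcsc_variant,transferred,twilight,provider passed to
#'   [course_spec()].
#' @param trajectories if `TRUE`, per-step positions are returned (use a
#'   small `n`).
#' @param overshoot_km overshoot termination distance south of the goal
#'   latitude (km).
#' @return object of class `population_result`: `arrival_fraction`, `n`,
#'   `status` (factor counts), `arrival_day`, `steps_used`,
#'   `mean_step_direction_sd` (realized per-step deviation, deg), and
#'   optionally `trajectories` (a long data frame).
#' @export
run_population <- function(route, course, alpha0,
                           prec = precision_spec(), sched = schedule(),
                           n = 10000, flight_speed_ms = 12.5, seed = NULL,
                           tcsc_variant = "classic", transferred = NULL,
                           twilight = "sunset",
                           provider = field_provider("dipole"),
                           trajectories = FALSE, overshoot_km = 1000) {
  if (inherits(route, "route_geometry")) {
    route <- list(natal_lat = route$natal[["lat"]], natal_lon = route$natal[["lon"]],
                  goal_lat = route$goal[["lat"]], goal_lon = route$goal[["lon"]],
                  goal_radius_km = route$goal_radius_km)
  }
  if (!is.null(seed)) set.seed(seed)
  spec <- course_spec(course, alpha0, route$natal_lat, route$natal_lon,
                      depart_day = sched$depart_mean,
                      tcsc_variant = tcsc_variant, transferred = transferred,
                      twilight = twilight, provider = provider)
  n_H <- sched$flight_hours
  r_step <- 3.6 * flight_speed_ms * n_H / R_EARTH
  r_hour <- r_step / n_H
  goal_phi <- .rad(route$goal_lat); goal_lam <- .rad(route$goal_lon)
  goal_r <- route$goal_radius_km / R_EARTH
  overshoot_phi <- goal_phi - overshoot_km / R_EARTH
  dec_f <- seq(0.1, 1, by = 0.1) * n_H # decile times in hours

  # per-individual state
  phi <- rep(.rad(route$natal_lat), n)
  lam <- rep(.rad(route$natal_lon), n)
  day <- round(stats::rnorm(n, sched$depart_mean, sched$depart_sd))
  while (any(bad <- day < 1)) {
    day[bad] <- round(stats::rnorm(sum(bad), sched$depart_mean, sched$depart_sd))
  }
  alpha0i <- .rad(spec$alpha0) + .rvm_rad(n, 0, .kappa_of(prec$individual))
  status <- integer(n)        # 0 active 1 arrived 2 overshot 3 timed_out
  steps <- integer(n)
  bout <- integer(n)
  arrival_day <- rep(NA_real_, n)
  last_mu <- alpha0i # expected (preferred) heading of the last flight-step
  dir_sq_sum <- 0; dir_n <- 0  # realized per-step deviation bookkeeping

  sun_course <- spec$course %in% c("fixed_sun", "tcsc")
  twl_sign <- if (spec$twilight == "sunset") 1 else -1
  k_mag <- if (spec$course == "magnetoclinic") {
    sin(alpha0i) / tan(.rad(spec$phi_m0))
  } else NULL
  # per-individual sun imprint at each individual's own departure date
  if (sun_course) {
    th0 <- twl_sign * .theta_s_rad(phi, .rad(solar_declination(day)))
    alpha_s <- alpha0i - th0
    aref <- alpha0i; thref <- th0; lref <- lam; sref_sin <- sin(phi)
    need_reset <- rep(FALSE, n)
  }
  dr <- if (is.null(prec$step) && prec$drift > 0) {
    calibrate_drift(prec$drift, n_H, prec$drift_autocorr)
  } else list(hourly_sd = 0)

  traj <- if (trajectories) vector("list", sched$max_steps) else NULL

  iter <- 0L
  max_iter <- sched$max_steps + 200L
  while (any(status == 0) && iter < max_iter) {
    iter <- iter + 1L
    act <- which(status == 0)

    # expected departure headings
    if (sun_course) {
      th <- twl_sign * .theta_s_rad(phi[act], .rad(solar_declination(day[act])))
      nosun <- is.na(th)
      if (any(nosun)) { # postpone departure by one day where no twilight
        idx <- act[nosun]
        day[idx] <- day[idx] + 1
        status[idx][day[idx] > sched$max_arrival_day] <- 3L
        act <- act[!nosun]
        th <- th[!nosun]
        if (!length(act)) next
      }
      if (spec$course == "tcsc" && any(need_reset[act])) {
        ri <- act[need_reset[act]]
        aref[ri] <- last_mu[ri]
        thref[ri] <- (twl_sign * .theta_s_rad(phi[ri], .rad(solar_declination(day[ri]))))
        lref[ri] <- lam[ri]
        sref_sin[ri] <- sin(phi[ri])
        need_reset[ri] <- FALSE
      }
    }
    mu <- switch(spec$course,
      geographic_lox = alpha0i[act],
      geomagnetic_lox = alpha0i[act] +
        .rad(spec$provider(.deg(phi[act]), .deg(lam[act]), day[act])$declination),
      magnetoclinic = .magnetoclinic_rad_k(k_mag[act], phi[act])$alpha,
      fixed_sun = alpha_s[act] + th,
      tcsc = {
        ss <- if (spec$tcsc_variant == "proximate") sin(phi[act]) else sref_sin[act]
        aref[act] + (th - thref[act]) + .wrap_pi(lam[act] - lref[act]) * ss
      }
    )

    fs <- .fly_step_core(phi[act], lam[act], mu, day[act], spec, prec, n_H,
                         r_hour, k_mag = k_mag[act], alpha0i = alpha0i[act],
                         drift_sd_rad = .rad(dr$hourly_sd),
                         drift_rho = prec$drift_autocorr)
    phi[act] <- fs$phi; lam[act] <- fs$lam
    last_mu[act] <- mu
    dev <- .wrap_pi(fs$dir - mu)
    dir_sq_sum <- dir_sq_sum + sum(dev^2); dir_n <- dir_n + length(dev)
    steps[act] <- steps[act] + 1L
    day[act] <- day[act] + 1

    # in-flight goal detection at each decile of the flight duration
    h0 <- pmin(floor(dec_f), n_H - 1e-9)
    arrived_step <- rep(FALSE, length(act))
    for (di in seq_along(dec_f)) {
      hh <- dec_f[di]
      j <- floor(hh + 1e-9); fr <- hh - j
      if (fr < 1e-9) { pj <- fs$PHI[, j + 1]; lj <- fs$LAM[, j + 1] }
      else {
        pj <- fs$PHI[, j + 1] * (1 - fr) + fs$PHI[, j + 2] * fr
        lj <- fs$LAM[, j + 1] + fr * .wrap_pi(fs$LAM[, j + 2] - fs$LAM[, j + 1])
      }
      hit <- !arrived_step & .gc_rad(pj, lj, goal_phi, goal_lam) <= goal_r
      arrived_step <- arrived_step | hit
    }
    ok_date <- day[act] - 1 <= sched$max_arrival_day
    newly <- arrived_step & ok_date
    status[act[newly]] <- 1L
    arrival_day[act[newly]] <- day[act[newly]] - 1

    still <- act[status[act] == 0]
    status[still][phi[still] < overshoot_phi] <- 2L
    still <- act[status[act] == 0]
    status[still][steps[still] >= sched$max_steps |
                  day[still] > sched$max_arrival_day] <- 3L

    if (trajectories) {
      traj[[min(iter, length(traj))]] <- data.frame(
        individual = act, step = steps[act], day = day[act] - 1,
        lat = .deg(phi[act]), lon = .deg(lam[act]),
        heading = .deg(fs$dir), status = status[act]
      )
    }

    # bout/stopover bookkeeping for those still migrating
    bout[act] <- bout[act] + 1L
    so <- act[bout[act] >= sched$flights_per_bout & status[act] == 0]
    if (length(so)) {
      dur <- pmax(1, round(stats::rnorm(length(so), sched$stopover_mean,
                                        sched$stopover_sd)))
      if (sun_course && spec$course == "tcsc") {
        if (spec$tcsc_variant == "retain_first_night") {
          # freeze the TCSC heading of the first stopover night as reference
          d1 <- day[so] # the night after arrival
          th1 <- twl_sign * .theta_s_rad(phi[so], .rad(solar_declination(d1)))
          ok <- !is.na(th1)
          ss <- if (spec$tcsc_variant == "proximate") sin(phi[so]) else sref_sin[so]
          a1 <- aref[so] + (th1 - thref[so]) + .wrap_pi(lam[so] - lref[so]) * ss
          aref[so][ok] <- a1[ok]
          thref[so][ok] <- th1[ok]
          lref[so][ok] <- lam[so][ok]
          sref_sin[so][ok] <- sin(phi[so][ok])
          need_reset[so][!ok] <- TRUE
        } else {
          need_reset[so] <- TRUE
        }
      }
      day[so] <- day[so] + dur
      bout[so] <- 0L
    }
  }
  status[status == 0] <- 3L

  res <- list(
    arrival_fraction = mean(status == 1),
    n = n,
    status = c(arrived = sum(status == 1), overshot = sum(status == 2),
               timed_out = sum(status == 3)),
    arrival_day = arrival_day,
    steps_used = steps,
    mean_step_direction_sd = if (dir_n) .deg(sqrt(dir_sq_sum / dir_n)) else NA_real_,
    course = course, alpha0 = alpha0, seed = seed
  )
  if (trajectories) res$trajectories <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  structure(res, class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result> %s alpha0=%.1f: %.1f%% arrival (n=%d)\n",
              x$course, x$alpha0, 100 * x$arrival_fraction, x$n))
  cat(sprintf("  arrived %d / overshot %d / timed out %d; realized step sd %.1f deg\n",
              x$status[["arrived"]], x$status[["overshot"]],
              x$status[["timed_out"]], x$mean_step_direction_sd))
  invisible(x)
}

#' Optimize the inherited initial heading
#'
#' Maximizes arrival fraction over the single inherited heading: a coarse
#' grid scan followed by golden-section refinement
#' ([stats::optimize()]) on the best bracket. The stochastic objective is
#' stabilized by common random numbers (every candidate heading re-uses
#' the same seed).
#'
#' @inheritParams run_population
#' @param bounds heading bounds in degrees (default East to West, -90 to
#'   90; NE to NW, -145 to 145, for sun-compass courses which may start
#'   with northward components).
#' @param coarse_step grid spacing of the initial scan (deg).
#' @param seed master seed (required: it drives the common random numbers).
#' @return list with `heading` (deg), `arrival_fraction`, `scan` (the
#'   coarse-grid data frame) and `converged`.
#' @export
optimize_heading <- function(route, course, prec = precision_spec(),
                             sched = schedule(), n = 2000,
                             flight_speed_ms = 12.5, seed = 1,
                             bounds = NULL, coarse_step = 5, ...) {
  if (is.null(bounds)) {
    bounds <- if (course %in% c("fixed_sun", "tcsc")) c(-145, 145) else c(-90, 90)
  }
  obj <- function(a) {
    run_population(route, course, a, prec, sched, n = n,
                   flight_speed_ms = flight_speed_ms, seed = seed,
                   ...)$arrival_fraction
  }
  grid <- seq(bounds[1], bounds[2], by = coarse_step)
  vals <- vapply(grid, obj, numeric(1))
  if (all(vals == 0)) {
    return(list(heading = NA_real_, arrival_fraction = 0,
                scan = data.frame(heading = grid, arrival = vals),
                converged = FALSE))
  }
  best <- grid[which.max(vals)]
  lo <- max(bounds[1], best - coarse_step)
  hi <- min(bounds[2], best + coarse_step)
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 0.25)
  if (opt$objective < max(vals)) {
    opt <- list(maximum = best, objective = max(vals))
  }
  list(heading = opt$maximum, arrival_fraction = opt$objective,
       scan = data.frame(heading = grid, arrival = vals), converged = TRUE)
}

#' Generic-migrant longitudinal feasibility scan
#'
#' For a generic migrant between two latitudes in a dipole field, scans
#' inherited initial headings: each heading's error-free trajectory defines
#' the realized goal longitude (where it crosses the goal latitude), and a
#' stochastic population is then simulated toward that goal. The maximal
#' feasible longitudinal migration distance is the largest longitude span
#' whose arrival fraction meets the threshold.
#'
#' @param lat_from,lat_to departure and goal latitudes (deg).
#' @param course,prec,sched,n,flight_speed_ms,seed,... as [run_population()].
#' @param headings candidate initial headings (deg from South); default a
#'   0.5-degree grid from East (-90) to West (90).
#' @param goal_radius_km goal radius (default 500 km).
#' @param arrival_threshold feasibility threshold on arrival fraction
#'   (default 0.25).
#' @return object of class `generic_scan`: data frame `scan` (heading,
#'   goal_lon, longitudinal span in degrees and km, arrival fraction,
#'   feasible), plus `max_feasible_deg` / `max_feasible_km`.
#' @export
generic_migrant_scan <- function(lat_from = 65, lat_to = 0, course,
                                 prec = precision_spec(), sched = schedule(),
                                 n = 1000, flight_speed_ms = 12.5, seed = 1,
                                 headings = seq(-90, 90, by = 0.5),
                                 goal_radius_km = 500,
                                 arrival_threshold = 0.25, ...) {
  ef_sched <- schedule(sched$flights_per_bout, sched$stopover_mean, 0,
                       sched$flight_hours, sched$depart_mean, 0,
                       sched$max_steps, sched$max_arrival_day)
  ef_prec <- precision_spec(individual = 0)
  rows <- lapply(headings, function(a) {
    gl <- .error_free_goal_lon(lat_from, lat_to, course, a, ef_sched,
                               flight_speed_ms, ...)
    if (is.na(gl)) {
      return(data.frame(heading = a, goal_lon = NA_real_, span_deg = NA_real_,
                        span_km = NA_real_, arrival = 0, feasible = FALSE))
    }
    route <- list(natal_lat = lat_from, natal_lon = 0, goal_lat = lat_to,
                  goal_lon = gl, goal_radius_km = goal_radius_km)
    pr <- run_population(route, course, a, prec, sched, n = n,
                         flight_speed_ms = flight_speed_ms, seed = seed, ...)
    span <- abs(.deg(.wrap_pi(.rad(gl))))
    data.frame(heading = a, goal_lon = gl, span_deg = span,
               span_km = .rad(span) * cos(.rad(lat_to)) * R_EARTH,
               arrival = pr$arrival_fraction,
               feasible = pr$arrival_fraction >= arrival_threshold)
  })
  scan <- do.call(rbind, rows)
  feas <- scan[scan$feasible, , drop = FALSE]
  structure(list(
    scan = scan, course = course,
    max_feasible_deg = if (nrow(feas)) max(feas$span_deg) else 0,
    max_feasible_km = if (nrow(feas)) max(feas$span_km) else 0,
    arrival_threshold = arrival_threshold
  ), class = "generic_scan")
}

#' @export
print.generic_scan <- function(x, ...) {
  cat(sprintf(
    "<generic_scan> %s: max feasible longitudinal span %.1f deg (%.0f km) at >= %.0f%% arrival\n",
    x$course, x$max_feasible_deg, x$max_feasible_km, 100 * x$arrival_threshold))
  invisible(x)
}

# error-free single-trajectory goal longitude: where the course first
# crosses the goal latitude (linear interpolation between hourly points)
.error_free_goal_lon <- function(lat_from, lat_to, course, alpha0, sched,
                                 flight_speed_ms, tcsc_variant = "classic",
                                 transferred = NULL, twilight = "sunset",
                                 provider = field_provider("dipole")) {
  route <- list(natal_lat = lat_from, natal_lon = 0, goal_lat = lat_to,
                goal_lon = 0, goal_radius_km = 1e-6)
  spec <- course_spec(course, alpha0, lat_from, 0, sched$depart_mean,
                      tcsc_variant = tcsc_variant, transferred = transferred,
                      twilight = twilight, provider = provider)
  n_H <- sched$flight_hours
  r_hour <- 3.6 * flight_speed_ms * n_H / R_EARTH / n_H
  phi <- .rad(lat_from); lam <- 0; day <- sched$depart_mean
  goal_phi <- .rad(lat_to)
  twl_sign <- if (twilight == "sunset") 1 else -1
  k_mag <- if (course == "magnetoclinic") {
    sin(.rad(alpha0)) / tan(.rad(spec$phi_m0))
  } else NA
  if (course %in% c("fixed_sun", "tcsc")) {
    th0 <- twl_sign * .theta_s_rad(phi, .rad(solar_declination(day)))
    alpha_s <- .rad(alpha0) - th0
    aref <- .rad(alpha0); thref <- th0; lref <- 0; sref_sin <- sin(phi)
  }
  bout <- 0L
  prev_dir <- .rad(alpha0)
  for (i in seq_len(sched$max_steps)) {
    th <- if (course %in% c("fixed_sun", "tcsc")) {
      twl_sign * .theta_s_rad(phi, .rad(solar_declination(day)))
    } else NA
    if (course %in% c("fixed_sun", "tcsc") && is.na(th)) { day <- day + 1; next }
    mu <- switch(course,
      geographic_lox = , geomagnetic_lox = .rad(alpha0),
      magnetoclinic = .magnetoclinic_rad_k(k_mag, phi)$alpha,
      fixed_sun = alpha_s + th,
      tcsc = {
        ss <- if (spec$tcsc_variant == "proximate") sin(phi) else sref_sin
        aref + (th - thref) + .wrap_pi(lam - lref) * ss
      }
    )
    p0 <- phi; l0 <- lam
    for (h in seq_len(n_H)) {
      if (course == "magnetoclinic") mu <- .magnetoclinic_rad_k(k_mag, phi)$alpha
      s <- .step_rad(phi, lam, mu, r_hour)
      if (s$phi <= goal_phi) { # crossed the goal latitude this hour
        f <- (phi - goal_phi) / (phi - s$phi)
        return(.deg(.wrap_pi(lam + f * .wrap_pi(s$lam - lam))))
      }
      phi <- s$phi; lam <- s$lam
      if (abs(phi) >= pi / 2 - 1e-6) return(NA_real_)
    }
    prev_mu <- mu # preferred heading retained on arrival at stopover
    day <- day + 1
    bout <- bout + 1L
    if (bout >= sched$flights_per_bout) {
      if (course == "tcsc") {
        if (spec$tcsc_variant == "retain_first_night") {
          th1 <- twl_sign * .theta_s_rad(phi, .rad(solar_declination(day)))
          if (!is.na(th1)) {
            ss <- sref_sin
            aref <- aref + (th1 - thref) + .wrap_pi(lam - lref) * ss
            thref <- th1; lref <- lam; sref_sin <- sin(phi)
          }
        } else {
          # reset at next departure: retain realized previous direction
          day2 <- day + max(1, round(sched$stopover_mean))
          th1 <- twl_sign * .theta_s_rad(phi, .rad(solar_declination(day2)))
          if (!is.na(th1)) {
            aref <- prev_mu; thref <- th1; lref <- lam; sref_sin <- sin(phi)
          }
        }
      }
      day <- day + max(1, round(sched$stopover_mean))
      bout <- 0L
    }
  }
  NA_real_
}
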