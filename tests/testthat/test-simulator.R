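test_that("precision and schedule constructors validate their inputs", {
  expect_error(precision_spec(detect = -1))
  expect_error(precision_spec(step = 20, maintain = 10), "exclusive")
  expect_silent(precision_spec(step = 20))
  expect_error(schedule(flights_per_bout = 0))
})

test_that("error-free due-South migration arrives surely in the error-free step count", {
  route <- due_south_route()
  r <- run_population(route, "geographic_lox", 0, precision_spec(individual = 0),
                      schedule(max_steps = 40), n = 300, seed = 4)
  expect_equal(r$arrival_fraction, 1)
  expect_true(all(r$steps_used == error_free_steps(route)))
  expect_equal(r$mean_step_direction_sd, 0, tolerance = 1e-8)
})

test_that("identical master seeds give identical population results", {
  route <- due_south_route()
  prec <- precision_spec(detect = 15, maintain = 15, drift = 10, individual = 2.5)
  r1 <- run_population(route, "geographic_lox", 0, prec, schedule(max_steps = 30),
                       n = 400, seed = 99)
  r2 <- run_population(route, "geographic_lox", 0, prec, schedule(max_steps = 30),
                       n = 400, seed = 99)
  expect_identical(r1$arrival_fraction, r2$arrival_fraction)
  expect_identical(r1$steps_used, r2$steps_used)
  expect_identical(r1$arrival_day, r2$arrival_day)
})

test_that("within-step error mechanics: many-wrongs averaging vs the cue-transfer penalty", {
  set.seed(21)
  n <- 6000; nH <- 8; s <- 16
  spec_nt <- course_spec("geographic_lox", 0, 45, transferred = FALSE)
  r_nt <- fly_step(spec_nt, rep(45, n), 0,
                   prec = precision_spec(detect = s, maintain = s, individual = 0),
                   n_H = nH)
  # non-transferred: hourly redetermination averages errors ~ sigma/sqrt(nH)
  expect_equal(sd(r_nt$direction_deg), s / sqrt(nH), tolerance = 0.05 * s)
  spec_t <- course_spec("geographic_lox", 0, 45, transferred = TRUE)
  r_t <- fly_step(spec_t, rep(45, n), 0,
                  prec = precision_spec(detect = s, transfer = s, maintain = s,
                                        individual = 0),
                  n_H = nH)
  # transferred: detection + transfer errors are not averaged away
  expected_t <- sqrt(s^2 + s^2 + s^2 / nH)
  expect_equal(sd(r_t$direction_deg), expected_t, tolerance = 0.06 * expected_t)
  expect_gt(sd(r_t$direction_deg), sd(r_nt$direction_deg))
})

test_that("drift calibration hits its per-step target and scales monotonically", {
  expect_equal(calibrate_drift(0, 8)$hourly_sd, 0)
  d15 <- calibrate_drift(15, 8, 0.5)
  expect_equal(d15$realized, 15, tolerance = 0.3)
  d30 <- calibrate_drift(30, 8, 0.5)
  expect_gt(d30$hourly_sd, d15$hourly_sd)
})

test_that("arrival fraction is non-increasing in the lumped per-step deviation", {
  route <- due_south_route()
  sig <- c(5, 20, 40, 60)
  arr <- vapply(sig, function(s) {
    run_population(route, "geographic_lox", 0,
                   precision_spec(individual = 0, step = s),
                   schedule(max_steps = 40), n = 1000, seed = 31)$arrival_fraction
  }, numeric(1))
  expect_true(all(diff(arr) <= 0.02)) # monotone within Monte-Carlo noise
  expect_gt(arr[1], 0.95)
  # with a tiny goal, extreme per-step error leaves arrival near zero
  tiny <- route; tiny$goal_radius_km <- 20
  a60 <- run_population(tiny, "geographic_lox", 0,
                        precision_spec(individual = 0, step = 60),
                        schedule(max_steps = 40), n = 1000,
                        seed = 31)$arrival_fraction
  expect_lt(a60, 0.05)
})

test_that("transferred courses never beat their non-transferred twin", {
  route <- due_south_route()
  prec_c <- precision_spec(detect = 20, transfer = 20, maintain = 20,
                           individual = 0)
  a_t <- run_population(route, "geographic_lox", 0, prec_c,
                        schedule(max_steps = 40), n = 1500, seed = 8,
                        transferred = TRUE)$arrival_fraction
  a_nt <- run_population(route, "geographic_lox", 0, prec_c,
                         schedule(max_steps = 40), n = 1500, seed = 8,
                         transferred = FALSE)$arrival_fraction
  expect_lte(a_t, a_nt)
})

test_that("heading optimization finds the symmetric optimum deterministically", {
  route <- due_south_route()
  prec <- precision_spec(individual = 0, step = 20)
  o1 <- optimize_heading(route, "geographic_lox", prec,
                         schedule(max_steps = 40), n = 500, seed = 5,
                         bounds = c(-40, 40), coarse_step = 10)
  expect_true(o1$converged)
  expect_lt(abs(o1$heading), 6) # symmetric scenario: optimum ~ due South
  o2 <- optimize_heading(route, "geographic_lox", prec,
                         schedule(max_steps = 40), n = 500, seed = 5,
                         bounds = c(-40, 40), coarse_step = 10)
  expect_identical(o1$heading, o2$heading)
  # shifting the goal West moves the optimum to westward headings
  route_w <- route; route_w$goal_lon <- -10
  o3 <- optimize_heading(route_w, "geographic_lox", prec,
                         schedule(max_steps = 40), n = 500, seed = 5,
                         bounds = c(-40, 40), coarse_step = 10)
  expect_gt(o3$heading, o1$heading)
})

test_that("TCSC populations complete a high-latitude eastward route", {
  route <- list(natal_lat = 65, natal_lon = 0, goal_lat = 0, goal_lon = 50,
                goal_radius_km = 500)
  prec <- precision_spec(detect = 15, transfer = 15, maintain = 15,
                         individual = 2.5)
  gl <- compasscourse:::.error_free_goal_lon(
    65, 0, "tcsc", -45, schedule(stopover_sd = 0, depart_sd = 0), 12.5)
  route$goal_lon <- gl
  r <- run_population(route, "tcsc", -45, prec, schedule(), n = 500, seed = 12)
  expect_gt(r$arrival_fraction, 0.3)
})
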