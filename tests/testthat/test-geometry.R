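test_that("planar step updates follow the stepwise movement equations", {
  # due-South step: latitude decreases by the arc length
  p <- step_position(deg(0.5), 0, 0, 0.1 * R_EARTH)
  expect_equal(unname(p["lat"]), deg(0.4), tolerance = 1e-12)
  expect_equal(unname(p["lon"]), 0)
  # westward (alpha = +90) on the equator: longitude decreases by the arc
  p <- step_position(0, 0, 90, 0.1 * R_EARTH)
  expect_equal(unname(p["lon"]), deg(-0.1), tolerance = 1e-9)
  expect_equal(unname(p["lat"]), 0, tolerance = 1e-9)
  # at 60N the longitude change is magnified by 1/cos(60) = 2
  p <- step_position(60, 0, 90, 0.1 * R_EARTH)
  expect_equal(unname(p["lon"]), deg(-0.2), tolerance = 1e-9)
  # pole crossing is outside the model domain
  expect_error(step_position(89, 0, 180, 500), "pole")
  expect_error(step_position(45, 0, 0, -10))
})

test_that("mirrored headings give mirror-image longitudes", {
  for (a in c(20, 55, 80)) {
    p1 <- step_position(50, 10, a, 400)
    p2 <- step_position(50, 10, -a, 400)
    expect_equal(unname(p1["lat"]), unname(p2["lat"]))
    expect_equal(unname(p1["lon"]) - 10, -(unname(p2["lon"]) - 10),
                 tolerance = 1e-12)
  }
})

test_that("sub-stepping converges to the single step on the equator", {
  # along the equator the planar update is exact, so any sub-stepping of a
  # constant heading reproduces the single step to rounding error
  one <- step_position(0, 0, 90, 800)
  for (N in c(2, 8, 32)) {
    p <- c(lat = 0, lon = 0)
    for (i in seq_len(N)) p <- step_position(p["lat"], p["lon"], 90, 800 / N)
    expect_lt(abs(unname(p["lon"]) - unname(one["lon"])), 1e-10)
    expect_lt(abs(unname(p["lat"])), 1e-12)
  }
})

test_that("great-circle solutions use the package Earth radius", {
  gc <- great_circle(0, 0, 0, 90)
  expect_equal(gc$distance_km, pi * R_EARTH / 2, tolerance = 0.1)
  expect_equal(gc$bearing_initial, 90)
  gc2 <- great_circle(10, 0, -10, 0)
  expect_equal(gc2$bearing_initial, 180)
  # distance symmetric under endpoint swap
  expect_equal(great_circle(52, -3, 17, 31)$distance_km,
               great_circle(17, 31, 52, -3)$distance_km)
  expect_error(great_circle(5, 5, 5, 5))
  expect_error(great_circle(10, 0, -10, 180))
})

test_that("the Mercator factor is the latitude-averaged secant", {
  expect_equal(mercator_factor(65, 0), 1.328, tolerance = 5e-4)
  expect_equal(mercator_factor(0, 0), 1)
  # numeric quadrature oracle
  for (band in list(c(45, 25), c(70, 10), c(30, -20))) {
    quad <- integrate(function(x) 1 / cos(x), rad(band[2]), rad(band[1]),
                      rel.tol = 1e-12)$value / (rad(band[1]) - rad(band[2]))
    expect_equal(mercator_factor(band[1], band[2]), quad, tolerance = 1e-9)
  }
})

test_that("the spherical-geometry factor interpolates between 1 and L", {
  expect_equal(geometry_factor(1.5, 0), 1)
  expect_equal(geometry_factor(1.5, 90), 1.5)
  expect_equal(geometry_factor(1.328, 45), 1.176, tolerance = 5e-4)
  # monotone in |sin(heading)| and in L
  h <- c(0, 15, 30, 45, 60, 75, 90)
  expect_true(all(diff(geometry_factor(1.4, h)) > 0))
  expect_true(all(diff(sapply(c(1, 1.2, 1.5, 2), geometry_factor,
                              mean_heading_deg = 40)) > 0))
})

test_that("goal breadths reproduce the published species values", {
  expect_equal(round(goal_breadths(36.9, 100, 3290)$beta_adj, 2), 0.18)
  expect_equal(round(goal_breadths(7.4, 800, 3370)$beta_adj, 2), 0.65)
  b <- goal_breadths(10, 500, 3000, mean_heading_deg = 37, lat_arrival_deg = 0)
  expect_equal(b$beta_A, b$beta) # equatorial arrival leaves beta unchanged
  expect_error(goal_breadths(10, 500, 400))
})

test_that("heading/bearing conversions are exact and invertible", {
  expect_equal(alpha_to_bearing(39), 219)
  expect_equal(bearing_to_alpha(108), -72)
  for (b in seq(0, 350, by = 35)) {
    expect_equal(alpha_to_bearing(bearing_to_alpha(b)), b %% 360)
    expect_equal(alpha_to_bearing(bearing_to_alpha(b, "S"), "S"), b %% 360)
  }
})

test_that("route geometry bundles distances, factors and breadths coherently", {
  rg <- route_geometry(45, 0, 25, 0, 500, r_step_km = 360)
  expect_equal(rg$G_gc, 1, tolerance = 1e-6)
  expect_equal(rg$alpha_initial, 0, tolerance = 1e-6)
  rg2 <- route_geometry(60, 0, 50, -40, 500, r_step_km = 360)
  expect_gt(rg2$G_lox, 1)
  expect_gt(abs(rg2$alpha_lox), 45)
})
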