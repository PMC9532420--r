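test_that("all five courses return the inherited heading at the natal site on departure", {
  lat0 <- 52; day0 <- 250; a0 <- 23
  for (crs in c("geographic_lox", "geomagnetic_lox", "magnetoclinic",
                "fixed_sun", "tcsc")) {
    spec <- course_spec(crs, a0, lat0, 0, depart_day = day0)
    h <- switch(crs,
      geographic_lox = heading_geographic_lox(spec),
      geomagnetic_lox = heading_geomagnetic_lox(spec, lat0),
      magnetoclinic = as.numeric(heading_magnetoclinic(spec, lat0)),
      fixed_sun = heading_fixed_sun(spec, lat0, day0),
      tcsc = heading_tcsc(spec, clock_state(a0, spec$theta_s0, 0, lat0),
                          lat0, 0, day0)
    )
    expect_equal(h, a0, tolerance = 1e-10, label = crs)
  }
})

test_that("geomagnetic loxodromes track declination additively", {
  spec <- course_spec("geomagnetic_lox", 30, 55)
  expect_equal(heading_geomagnetic_lox(spec, declination_deg = 0), 30)
  expect_equal(heading_geomagnetic_lox(spec, declination_deg = 10), 40)
  ramp <- seq(-15, 15, by = 5)
  expect_equal(heading_geomagnetic_lox(spec, declination_deg = ramp), 30 + ramp)
})

test_that("magnetoclinic headings preserve the transverse inclination projection", {
  spec <- course_spec("magnetoclinic", 45, 40)
  expect_equal(as.numeric(heading_magnetoclinic(spec, 30)), 29.1,
               tolerance = 0.05)
  expect_equal(as.numeric(heading_magnetoclinic(spec, 40)), 45,
               tolerance = 1e-9)
  # inclination increasing en route triggers the East/West fallback
  spec80 <- course_spec("magnetoclinic", 80, 40)
  h <- heading_magnetoclinic(spec80, 44)
  expect_true(attr(h, "fallback"))
  expect_equal(as.numeric(h), 90) # sin(alpha0) > 0: due magnetic West
  # general (inclination) form equals the dipole closed form under the dipole
  for (lat in c(35, 25, 15)) {
    closed <- deg(asin(sin(rad(45)) * tan(rad(lat)) / tan(rad(40))))
    expect_equal(as.numeric(heading_magnetoclinic(spec, lat)), closed,
                 tolerance = 1e-10)
  }
})

test_that("fixed sun-compass headings are a constant twilight-azimuth offset", {
  spec <- course_spec("fixed_sun", 10, 50, depart_day = 240)
  # at an equinox the azimuth is 90 anywhere, so heading = alpha_s + 90
  expect_equal(heading_fixed_sun(spec, 35, 265), spec$alpha_s + 90,
               tolerance = 0.7)
  # reflects the declination antisymmetry via the azimuth
  d1 <- heading_fixed_sun(spec, 50, 240) - spec$alpha_s
  expect_equal(d1, sunset_azimuth(50, 240))
})

test_that("TCSC clock-shift bookkeeping self-corrects longitude errors", {
  spec <- course_spec("tcsc", 0, 55, 0, depart_day = 258)
  ck <- clock_state(0, spec$theta_s0, 0, 55)
  # no displacement, same date and latitude: heading unchanged
  expect_equal(heading_tcsc(spec, ck, 55, 0, 258), 0)
  # eastward displacement of 28 deg at 55N: ~23 deg westward offset
  expect_equal(heading_tcsc(spec, ck, 55, 28, 258), 22.9, tolerance = 0.1)
  # the offset opposes the sign of the longitude error
  expect_lt(heading_tcsc(spec, ck, 55, -10, 258), 0)
  expect_gt(heading_tcsc(spec, ck, 55, 10, 258), 0)
  # proximate variant gauges the rate from the current latitude
  specp <- course_spec("tcsc", 0, 55, 0, depart_day = 258,
                       tcsc_variant = "proximate")
  expect_equal(heading_tcsc(specp, ck, 40, 28, 258) -
                 (sunset_azimuth(40, 258) - spec$theta_s0),
               28 * sin(rad(40)), tolerance = 1e-9)
})

test_that("the small-displacement self-correction prediction is delta-lambda sin(lat)", {
  expect_equal(round(predicted_self_correction(28, 55)), 23)
  expect_equal(predicted_self_correction(40, 0), 0)
  expect_equal(predicted_self_correction(10, 30), 5)
})
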