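test_that("loxodrome sensitivity is identically zero and matches the oracle", {
  expect_identical(sensitivity_loxodrome(), 0)
  g <- sensitivity_grid("geographic_lox")
  expect_true(all(g$derivative == 0))
  expect_equal(sensitivity_fd("geographic_lox", 40, 50), 0)
  expect_equal(sensitivity_fd("geomagnetic_lox", -70, 60), 0)
})

test_that("analytic sensitivities agree with central finite differences", {
  lats <- seq(10, 62, length.out = 8)
  heads <- seq(-80, 80, length.out = 9)
  for (crs in c("magnetoclinic", "fixed_sun", "tcsc")) {
    for (p in lats) for (a in heads) {
      an <- switch(crs,
        magnetoclinic = sensitivity_magnetoclinic(a, p, 360),
        fixed_sun = sensitivity_fixed_sun(a, p, 213, 360),
        tcsc = sensitivity_tcsc(a, p, 213, 360, "classic")
      )
      if (!is.finite(an)) next
      fd <- sensitivity_fd(crs, a, p, 213, 360)
      expect_equal(an, fd, tolerance = 1e-5,
                   label = sprintf("%s lat %.0f head %.0f", crs, p, a))
    }
  }
  # proximate TCSC variant too
  expect_equal(sensitivity_tcsc(35, 50, 213, 360, "proximate"),
               sensitivity_fd("tcsc", 35, 50, 213, 360, variant = "proximate"),
               tolerance = 1e-7)
})

test_that("magnetoclinic sensitivity vanishes due South and diverges with latitude and E-W headings", {
  expect_equal(sensitivity_magnetoclinic(0, 45), 0)
  # the 1/(cos^2(lat) tan(lat)) structure diverges toward BOTH high and low
  # latitudes (minimum near 45)
  v <- sensitivity_magnetoclinic(40, c(50, 65, 75, 82))
  expect_true(all(diff(abs(v)) > 0))
  expect_gt(abs(sensitivity_magnetoclinic(40, 10)),
            abs(sensitivity_magnetoclinic(40, 35)))
  expect_gt(abs(sensitivity_magnetoclinic(75, 45)),
            abs(sensitivity_magnetoclinic(20, 45)))
  # at a due-East/West state the course rule has no interior solution
  expect_true(is.na(sensitivity_magnetoclinic(90, 45)))
  expect_gt(abs(sensitivity_magnetoclinic(89.9, 45)), 1)
})

test_that("sun-compass sensitivity is equinox-null, E/W-antisymmetric, and TCSC self-corrects", {
  # near the autumn equinox (declination ~ 0) fixed-sun sensitivity ~ 0
  expect_lt(abs(sensitivity_fixed_sun(45, 50, 265)), 1e-3)
  # sign flips East <-> West
  expect_equal(sensitivity_fixed_sun(35, 50, 213),
               -sensitivity_fixed_sun(-35, 50, 213), tolerance = 1e-6)
  # Southward TCSC at mid-latitude is negative (self-correcting), in the
  # 5-25% range
  s <- sensitivity_tcsc(0, 50, 213, 360)
  expect_lt(s, 0)
  expect_gt(100 * abs(s), 5)
  expect_lt(100 * abs(s), 25)
  # proximate third term: <= 0 and small relative to the clock-shift term
  for (p in seq(20, 60, by = 10)) for (a in seq(-60, 60, by = 20)) {
    r <- 360 / R_EARTH
    third <- sensitivity_tcsc(a, p, 213, 360, "proximate") -
      (sensitivity_fixed_sun(a, p, 213, 360) -
         r * cos(rad(a)) * sin(rad(p) - r * cos(rad(a))) / cos(rad(p)))
    second <- -r * cos(rad(a)) * sin(rad(p) - r * cos(rad(a))) / cos(rad(p))
    expect_lte(third, 1e-12)
    expect_lt(abs(third), abs(second))
  }
})

test_that("sensitivity grids mask undefined regions and export as tables", {
  g <- sensitivity_grid("fixed_sun", day = 213, lats = seq(0, 85, by = 5),
                        headings = seq(-60, 60, by = 20))
  # poleward of the no-sunset boundary (~72 on Aug 1) cells are masked;
  # sensitivity is evaluated at the post-step latitude, so allow one full
  # step (360 km ~ 3.24 deg) of southward displacement
  masked <- g$latitudes > no_sunset_latitude(213) + 3.3
  expect_true(all(is.na(g$derivative[masked, ])))
  expect_true(all(is.finite(g$derivative[g$latitudes < 70, ])))
  df <- as.data.frame(g)
  expect_named(df, c("lat", "heading", "value"))
  expect_equal(nrow(df), length(g$latitudes) * length(g$headings))
  path <- tempfile(fileext = ".tsv")
  write_sensitivity_grid(g, path)
  back <- read.delim(path)
  expect_equal(back$value, df$value)
})
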