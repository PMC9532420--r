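test_that("expected step counts scale by the inverse mean resultant length", {
  expect_equal(expected_steps(10, Inf), 10)
  expect_equal(expected_steps(10, 8.2), 10 / circular_length(8.2))
  kk <- c(1, 4, 8.2, 50)
  expect_true(all(diff(expected_steps(10, kk)) < 0))
  expect_warning(expected_steps(10, 1e-8))
})

test_that("the planar-normal arrival probability matches direct evaluation", {
  # direct erf evaluation: erf(0.1 * sqrt(25) / (sqrt(2) * rad(20))) = 0.8480
  expect_equal(performance_normal(0.1, 20, 25), 0.848, tolerance = 5e-4)
  expect_equal(performance_normal(10, 20, 25), 1, tolerance = 1e-9)
  expect_equal(performance_normal(0.1, 0, 25), 1)
  # Monte-Carlo mean-of-headings cross-check; the residual gap reflects
  # that sigma = 1/sqrt(kappa) slightly understates the true angular sd
  set.seed(2)
  m <- replicate(20000, mean(rad(rvonmises(25, 0, sigma_to_kappa(20)))))
  expect_lt(abs(mean(abs(m) <= 0.1) - performance_normal(0.1, 20, 25)), 0.02)
})

test_that("the generalized many-wrongs exponent has the stated limits", {
  expect_equal(eta_exponent(20, s = 0, b0 = 0), 0.5)
  expect_equal(eta_exponent(1e4, s = 1, b0 = 0.2), 0, tolerance = 1e-12)
  # larger scaled step distance increases eta when b0, rho > 0
  e <- eta_exponent(20, s = 0.5, b0 = 0.2, r_step_scaled = c(0.5, 1, 2),
                    rho = 1)
  expect_true(all(diff(e) > 0))
})

test_that("timely arrival follows the central limit theorem and a Monte-Carlo oracle", {
  expect_equal(timely_arrival(10, 40, 200), 1, tolerance = 1e-6)
  expect_equal(timely_arrival(10, 40, Inf), 1)
  # N0/Nmax above the mean resultant length: less than half arrive in time
  expect_lt(timely_arrival(38, 40, 4), 0.5)
  # Monte-Carlo: P(sum of cos of Nmax von Mises steps >= N0)
  set.seed(9)
  k <- 4; Nmax <- 50
  for (N0 in c(38, 42, 45)) {
    sims <- replicate(4000, sum(cos(rad(rvonmises(Nmax, 0, k)))) >= N0)
    expect_lt(abs(timely_arrival(N0, Nmax, k) - mean(sims)), 0.02,
              label = paste("N0 =", N0))
  }
})

test_that("full performance reduces to the planar form and is monotone", {
  # null params, G = 1, no individual variability, generous step budget
  for (s in c(10, 20, 30)) {
    full <- performance_full(0.22, 1, 8, 100, s)
    expect_equal(full, performance_normal(0.22, s, expected_steps(8, sigma_to_kappa(s))),
                 tolerance = 1e-6)
  }
  # g > 1 strictly lowers performance on zonal routes (G > 1)
  p1 <- performance_full(0.3, 1.3, 10, 40, 20, params = performance_params(g = 1))
  p2 <- performance_full(0.3, 1.3, 10, 40, 20, params = performance_params(g = 1.5))
  expect_lt(p2, p1)
  # monotone over a parameter lattice
  for (s in c(10, 25, 45)) for (G in c(1, 1.2, 1.5)) {
    base <- performance_full(0.3, G, 10, 40, s)
    expect_true(base >= 0 && base <= 1)
    expect_lte(performance_full(0.3, G, 10, 40, s + 5), base + 1e-12)
    expect_lte(performance_full(0.3, G + 0.2, 10, 40, s), base + 1e-12)
    expect_lte(performance_full(0.3, G, 10, 40, s, sigma_ind_deg = 5),
               base + 1e-12)
    expect_gte(performance_full(0.35, G, 10, 40, s), base - 1e-12)
    expect_gte(performance_full(0.3, G, 14, 56, s), base - 1e-12)
  }
})

test_that("AICc equals the small-sample Gaussian RSS formula", {
  routes <- species_route_table()
  set.seed(1)
  obs <- synthetic_performance_obs(routes, c(5, 10, 20, 30, 40, 50, 60),
                                   performance_params(g = 1.3, b0 = 0.1, s = 1),
                                   noise_sd = 0.01)
  fit <- fit_performance(obs)
  full <- fit$aicc_table[fit$aicc_table$subset == "g+b0+s", ]
  n <- nrow(obs); k <- 3 + 1
  expect_equal(full$aicc,
               n * log(full$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
})

test_that("regression recovers generating parameters and prunes null ones", {
  routes <- species_route_table()
  gen <- performance_params(g = 1.4, b0 = 0.15, s = 1.5)
  set.seed(33)
  obs <- synthetic_performance_obs(routes, c(5, 10, 20, 30, 40, 50, 60), gen,
                                   noise_sd = 0.005)
  fit <- fit_performance(obs)
  expect_true(all(c("g", "b0", "s") %in% fit$selected))
  expect_lt(abs(fit$params$g - 1.4), 0.05 * 1.4)
  expect_lt(abs(fit$params$b0 - 0.15), 0.05 * 0.15 + 0.01)
  expect_lt(abs(fit$params$s - 1.5), 0.05 * 1.5 + 0.05)
  expect_gt(fit$adj_r2, 0.99)
  # when g = 1 generated the data, AICc excludes g in the clear majority of
  # replicates (best-subset search keeps a spurious parameter more often
  # than a single pairwise comparison would: the stable rate is ~85%)
  set.seed(77)
  excl <- replicate(50, {
    o <- synthetic_performance_obs(routes, c(5, 10, 20, 30, 40, 50, 60),
                                   performance_params(g = 1, b0 = 0.15, s = 1.5),
                                   noise_sd = 0.01)
    f <- suppressWarnings(fit_performance(o))
    !("g" %in% f$selected)
  })
  expect_gte(mean(excl), 0.7)
})
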