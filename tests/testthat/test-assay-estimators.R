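test_that("transfer efficiency is T/(DRt) with censoring from zero plates", {
  est <- transfer_efficiency(1e4, 1e8, 1e8, t = 1)
  expect_equal(est$gamma, 1e-12)
  expect_false(est$censored)

  # zero colonies: the 0.5-colony rule gives a censored upper bound
  T0 <- density_from_plate(0, dilution = 1, volume = 0.1)
  expect_equal(as.numeric(T0), 5)
  cens <- transfer_efficiency(T0, 1e8, 1e8, t = 1)
  expect_true(cens$censored)
  expect_equal(cens$gamma, 5e-16)

  expect_error(transfer_efficiency(1, 0, 1e8, 1), "> 0")
  expect_error(transfer_efficiency(1, 1e8, 1e8, t = 0), "> 0")
})

test_that("transfer efficiency scales linearly in T and inversely in D, R, t", {
  base <- transfer_efficiency(2e4, 5e7, 8e7, t = 2)$gamma
  expect_equal(transfer_efficiency(6e4, 5e7, 8e7, t = 2)$gamma, 3 * base)
  expect_equal(transfer_efficiency(2e4, 1e8, 8e7, t = 2)$gamma, base / 2)
  expect_equal(transfer_efficiency(2e4, 5e7, 1.6e8, t = 2)$gamma, base / 2)
  expect_equal(transfer_efficiency(2e4, 5e7, 8e7, t = 4)$gamma, base / 2)
})

test_that("plate counts convert to densities with the 0.5-colony threshold", {
  d <- density_from_plate(100, dilution = 1e5, volume = 0.1)
  expect_equal(as.numeric(d), 1e8)
  expect_false(attr(d, "censored"))

  z <- density_from_plate(0, dilution = 1, volume = 0.1)
  expect_equal(as.numeric(z), 5)
  expect_true(attr(z, "censored"))

  expect_error(density_from_plate(-1), ">= 0")
  expect_error(density_from_plate(10, dilution = 0.5), ">= 1")

  # Poisson plating round-trip at moderate counts
  set.seed(14)
  true_density <- 3e6; dilution <- 1e3; volume <- 0.1
  rel <- replicate(300, {
    col <- rpois(1, true_density * volume / dilution) # ~300 colonies
    abs(as.numeric(density_from_plate(col, dilution, volume)) -
          true_density) / true_density
  })
  expect_lt(mean(rel), 2 / sqrt(true_density * volume / dilution))
})

test_that("max growth rate recovers a noiseless exponential exactly", {
  t <- seq(0, 24, by = 5 / 60)
  od <- 0.01 * exp(0.8 * t)
  est <- max_growth_rate(t, od)
  expect_equal(est$mu_max, 0.8, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-10)
  expect_true(est$window_start >= 2 && est$window_end <= 10)

  flat <- max_growth_rate(t, rep(0.5, length(t)))
  expect_equal(flat$mu_max, 0, tolerance = 1e-12)

  # log-slope invariance under positive scaling at zero blank
  est5 <- max_growth_rate(t, 5 * od)
  expect_equal(est5$mu_max, est$mu_max, tolerance = 1e-10)

  expect_error(max_growth_rate(t[1:5], od[1:5]), "fewer than")
  expect_error(max_growth_rate(t, rep(1e-5, length(t)), blank = 0),
               "fewer than")
})

test_that("max growth rate is recovered from noisy logistic curves", {
  errs <- vapply(1:100, function(s) {
    gc <- simulate_growth_curve(mu = 0.6, lag = 1, K_od = 1, od0 = 0.01,
                                noise_sd = 0.005, seed = s)
    (max_growth_rate(gc$times, gc$od)$mu_max - 0.6) / 0.6
  }, numeric(1))
  expect_gte(mean(abs(errs) < 0.05), 0.9)
})

test_that("proportion series cap at one and carry exact intervals", {
  out <- proportion_timeseries(c(1e6, 0, 5e6), c(1e6, 2e6, 4e6),
                               censored = c(FALSE, TRUE, FALSE))
  expect_equal(out$fraction, c(1, 0, 1))
  expect_true(attr(out, "any_censored"))
  expect_false(attr(proportion_timeseries(1, 2), "any_censored"))
  expect_error(proportion_timeseries(1, 0), "> 0")

  # interval coverage for a known fraction 0.3 with ~100 colonies
  set.seed(31)
  covered <- replicate(200, {
    sel <- rpois(1, 30); non <- rpois(1, 100)
    ci <- proportion_timeseries(sel * 10, non * 10,
                                colonies_sel = sel, colonies_nonsel = non)
    ci$lower <= 0.3 && ci$upper >= 0.3
  })
  expect_gte(mean(covered), 0.9)
})
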