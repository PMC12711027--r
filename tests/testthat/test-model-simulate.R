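test_that("the single-plasmid equilibrium is a fixed point of the flow", {
  p <- standard_params()
  eq <- as.numeric(single_plasmid_equilibrium(p))
  tr <- simulate_competition(p, initial = population_state(NW = eq),
                             t_max = 500, times = seq(0, 500, 50))
  expect_lt(max(abs(tr$NW - eq)), 1e-7)
  expect_lt(max(tr$N0 + tr$NM + tr$NWM), 1e-9)
})

test_that("structural neutrality: equal rates keep NW and NM identical", {
  p <- standard_params() # beta_W = beta_M, s_W = s_M
  init <- population_state(N0 = 0.1, NW = 0.4, NM = 0.4, NWM = 0.05)
  tr <- simulate_competition(p, initial = init, t_max = 1e3,
                             times = seq(0, 1e3, 5))
  expect_lt(max(abs(tr$NW - tr$NM)), 1e-8)
})

test_that("states stay non-negative and bounded for varied parameters", {
  set.seed(101)
  for (i in 1:8) {
    p <- model_params(rho = runif(1, 0.5, 2), c = runif(1, 0, 0.4),
                      gamma = runif(1, 0.01, 0.3), K = runif(1, 0.5, 2),
                      beta_W = runif(1, 0.1, 3), beta_M = runif(1, 0.1, 3),
                      s_W = runif(1, 0, 0.4), s_M = runif(1, 0, 0.4),
                      k = runif(1, 0.5, 1))
    tot0 <- runif(1, 0.05, 1.5) * p$K
    w <- diff(c(0, sort(runif(3)), 1))
    init <- population_state(N0 = tot0 * w[1], NW = tot0 * w[2],
                             NM = tot0 * w[3], NWM = tot0 * w[4])
    tr <- simulate_competition(p, initial = init, t_max = 200,
                               times = seq(0, 200, 2))
    expect_gte(min(tr$N0, tr$NW, tr$NM, tr$NWM), 0)
    tot <- tr$N0 + tr$NW + tr$NM + tr$NWM
    expect_lte(max(tot), max(tot0, p$K) + 1e-6)
  }
})

test_that("event-detected replacement time matches a brute-force dense scan", {
  p <- standard_params()
  for (a in c(1.5, 2)) {
    pa <- with_advantages(p, a_H = a)
    ev <- replacement_time(pa, t_max = 2e4)$time
    scan <- replacement_scan(pa, t_max = 2e4)
    expect_lt(abs(ev - scan) / scan, 0.01)
  }
})

test_that("a horizontal advantage of 2 replaces the wildtype at the frozen time", {
  p <- with_advantages(standard_params(), a_H = 2)
  r <- replacement_time(p)
  expect_true(r$replaced)
  # regression value from long-horizon integration at rtol 1e-8
  expect_equal(r$time, 2249.8988, tolerance = 1e-4)
})

test_that("no advantage means no replacement; reduced variant can coexist", {
  p <- standard_params()
  r <- replacement_time(p, t_max = 1e5)
  expect_false(r$replaced)
  expect_identical(r$time, Inf)

  # without displacement-on-reinfection, a weak horizontal advantage
  # settles into interior coexistence instead of replacing
  pa <- with_advantages(p, a_H = 1.2)
  tr <- simulate_competition(pa, t_max = 2e5, times = c(0, 1e5, 2e5),
                             coinfection_displacement = FALSE)
  expect_gt(tr$NW[3], 0.1)
  expect_equal(tr$NW[2], tr$NW[3], tolerance = 1e-5)
  # with it, the same advantage replaces
  expect_true(replacement_time(pa, t_max = 1e5)$replaced)
})

test_that("absolute-density and frequency criteria classify runs consistently", {
  p <- standard_params()
  freq <- replacement_criterion("relative_frequency", 0.01)
  for (a in c(1, 1.5)) {
    pa <- with_advantages(p, a_H = a)
    expect_identical(replacement_time(pa, t_max = 2e4)$replaced,
                     replacement_time(pa, criterion = freq,
                                      t_max = 2e4)$replaced)
  }
})

test_that("simulation inputs are validated", {
  p <- standard_params()
  expect_error(simulate_competition(p, t_max = -1), "positive")
  expect_error(simulate_competition(p, t_max = 10, times = c(5, 2)),
               "strictly increasing")
  expect_error(replacement_criterion(threshold = -1), "positive")
  expect_error(replacement_criterion("relative_frequency", threshold = 2),
               "< 1")
  expect_error(replacement_criterion(compartments = "N0"), "subset")
  # criterion already met at t = 0
  init <- population_state(N0 = 1, NW = 0.001, NM = 0, NWM = 0)
  r0 <- replacement_time(p, initial = init)
  expect_equal(r0$time, 0)
})

test_that("trajectories expose integrator metadata", {
  p <- standard_params()
  tr <- simulate_competition(p, t_max = 10)
  expect_s3_class(tr, "plasmid_trajectory")
  expect_equal(attr(tr, "rtol"), 1e-8)
  expect_equal(attr(tr, "atol"), 1e-10)
  expect_false(attr(tr, "replaced"))
  expect_true(is.unsorted(tr$time) == FALSE)
})
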