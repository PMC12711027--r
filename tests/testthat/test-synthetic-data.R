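test_that("generators are bit-identical under a fixed seed", {
  a <- simulate_coverage(seed = 8, plasmid_length = 5000,
                         deletion = c(1000, 3000))
  b <- simulate_coverage(seed = 8, plasmid_length = 5000,
                         deletion = c(1000, 3000))
  expect_identical(a$depth, b$depth)

  expect_identical(simulate_allele_counts(300, 0.4, seed = 2),
                   simulate_allele_counts(300, 0.4, seed = 2))
  expect_identical(simulate_conjugation(seed = 3, replicates = 2),
                   simulate_conjugation(seed = 3, replicates = 2))
  g1 <- simulate_growth_curve(seed = 4); g2 <- simulate_growth_curve(seed = 4)
  expect_identical(g1$od, g2$od)
})

test_that("coverage generator matches its analytic expectation per partition", {
  prof <- simulate_coverage(n_full = 2, n_streamlined = 6, chrom_depth = 40,
                            seed = 19)
  truth <- attr(prof, "truth")
  del <- truth$deletion
  inside <- prof$depth[del[1]:del[2]]
  outside <- prof$depth[-(del[1]:del[2])]
  expect_lt(abs(mean(inside) - 80), 3 * sqrt(80 / length(inside)))
  expect_lt(abs(mean(outside) - 320), 3 * sqrt(320 / length(outside)))

  # no streamlined copies: flat profile at n_full * chrom depth
  flat <- simulate_coverage(n_full = 1, n_streamlined = 0, chrom_depth = 60,
                            plasmid_length = 30000,
                            deletion = c(1000, 2000), seed = 20)
  expect_lt(abs(mean(flat$depth) - 60), 3 * sqrt(60 / 30000))

  # overdispersed depths inflate the variance
  od <- simulate_coverage(n_full = 1, n_streamlined = 0, chrom_depth = 60,
                          plasmid_length = 30000, deletion = c(1000, 2000),
                          overdispersion = 5, seed = 21)
  expect_gt(var(od$depth), 3 * var(flat$depth))
})

test_that("allele counts are binomial draws with degenerate edges", {
  expect_identical(simulate_allele_counts(200, 0, seed = 1)[["mutant"]], 0L)
  expect_identical(simulate_allele_counts(200, 1, seed = 1)[["ancestral"]],
                   0L)
  freqs <- vapply(1:100, function(s)
    simulate_allele_counts(500, 0.9, seed = s)[["mutant"]] / 500,
    numeric(1))
  expect_gte(mean(abs(freqs - 0.9) < 0.04), 0.95)
})

test_that("conjugation assays embed their generating truth", {
  null <- simulate_conjugation(gamma_true = 0, seed = 6)
  expect_identical(null$colonies_T, 0L)
  expect_true(null$censored)

  # short-time linearity: doubling gamma doubles the expected T
  t1 <- attr(simulate_conjugation(gamma_true = 1e-12, seed = 1),
             "truth")$final[["T"]]
  t2 <- attr(simulate_conjugation(gamma_true = 2e-12, seed = 1),
             "truth")$final[["T"]]
  expect_equal(t2 / t1, 2, tolerance = 1e-3)

  # estimator recovery against the generating rate
  assay <- simulate_conjugation(gamma_true = 1e-12, replicates = 4,
                                seed = 12)
  est <- mean(vapply(seq_len(4), function(i)
    transfer_efficiency(assay$T_obs[i], assay$D[i], assay$R[i],
                        assay$t[i])$gamma, numeric(1)))
  expect_equal(est, 1e-12, tolerance = 0.1)
})

test_that("growth curves reduce to exact exponential without noise or lag", {
  gc <- simulate_growth_curve(mu = 0.7, lag = 0, K_od = Inf, od0 = 0.01,
                              noise_sd = 0)
  est <- max_growth_rate(gc$times, gc$od)
  expect_equal(est$mu_max, 0.7, tolerance = 1e-10)

  # large K approaches the exponential limit over the fit range
  gk <- simulate_growth_curve(mu = 0.7, lag = 0, K_od = 1e6, od0 = 0.01,
                              noise_sd = 0)
  expect_equal(max_growth_rate(gk$times, gk$od)$mu_max, 0.7,
               tolerance = 1e-4)
})

test_that("trajectory observables report the wildtype-carrying fraction", {
  p <- standard_params()
  free <- simulate_competition(p, initial = population_state(N0 = 0.5),
                               t_max = 1, times = 0:1)
  expect_equal(observables_from_trajectory(free)$fraction, c(0, 0))

  allw <- simulate_competition(p, initial = population_state(NW = 0.5),
                               t_max = 1, times = 0:1)
  expect_equal(observables_from_trajectory(allw)$fraction, c(1, 1))

  # neutral competition: the marked (wildtype-carrying) fraction stays
  # symmetric with its mutant counterpart and plateaus rather than
  # trending to loss or fixation; plating noise scatters around it
  neut <- simulate_competition(p, initial = population_state(
    N0 = 0, NW = 0.44, NM = 0.44, NWM = 0.01), t_max = 96,
    times = seq(0, 96, 24))
  obs <- observables_from_trajectory(neut, n_colonies = 200, seed = 17)
  tot <- neut$N0 + neut$NW + neut$NM + neut$NWM
  fm <- (neut$NM + neut$NWM) / tot
  expect_equal(obs$fraction, fm, tolerance = 1e-8)
  expect_true(all(obs$fraction > 0.45 & obs$fraction < 0.65))
  expect_lt(max(abs(diff(tail(obs$fraction, 3)))), 0.01) # plateauing
  expect_lt(max(abs(obs$observed - obs$fraction)), 0.1)
})
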