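test_that("region means average per-base depth over interval unions", {
  rs <- region_set(a = data.frame(start = c(1, 8), end = c(3, 10)),
                   b = data.frame(start = 4, end = 7))
  prof <- coverage_profile(rep(6, 10))
  expect_equal(region_mean(prof, "a", rs), 6)
  expect_equal(region_mean(prof, "b", rs), 6)
  expect_error(region_mean(prof, "c", rs), "unknown region")

  # piecewise-constant profile over the default R1 regions
  d <- rep(10, 99378)
  amr <- region_set()$AMR
  for (i in seq_len(nrow(amr))) d[amr$start[i]:amr$end[i]] <- 1
  prof2 <- coverage_profile(d)
  expect_equal(region_mean(prof2, "backbone"), 10)
  expect_equal(region_mean(prof2, "AMR"), 1)
})

test_that("region means of Poisson profiles match expectation within 3 SE", {
  prof <- simulate_coverage(n_full = 1, n_streamlined = 9,
                            chrom_depth = 50, seed = 11)
  rs <- region_set()
  n_bb <- sum(rs$backbone$end - rs$backbone$start + 1)
  n_amr <- sum(rs$AMR$end - rs$AMR$start + 1)
  expect_lt(abs(region_mean(prof, "backbone") - 500),
            3 * sqrt(500 / n_bb))
  expect_lt(abs(region_mean(prof, "AMR") - 50), 3 * sqrt(50 / n_amr))
})

test_that("relative coverage is the ratio to chromosome depth", {
  expect_equal(relative_coverage(12, 12), 1)
  expect_equal(relative_coverage(0, 12), 0)
  expect_equal(relative_coverage(30, 10), 3) # ancestral-like 2-3 copies scale
  expect_error(relative_coverage(10, 0), "positive")
})

test_that("mixture deconvolution recovers copy numbers and clamps noise", {
  mix <- estimate_mixture(10, 1)
  expect_equal(mix$n_full, 1)
  expect_equal(mix$n_streamlined, 9)
  expect_equal(mix$r, 0.1)
  expect_equal(mix$streamlined_fraction, 0.9)

  pure <- estimate_mixture(2.5, 2.5)
  expect_equal(pure$n_streamlined, 0)
  expect_equal(pure$r, 1)

  noisy <- estimate_mixture(2.5, 2.7) # AMR above backbone: clamp
  expect_equal(noisy$r, 1)
  expect_equal(noisy$n_streamlined, 0)
  expect_equal(noisy$n_full + noisy$n_streamlined, noisy$backbone_rel)

  set.seed(3)
  for (i in 1:20) {
    b <- runif(1, 0.5, 12); a <- runif(1, 0, 14)
    m <- estimate_mixture(b, a)
    expect_equal(m$n_full + m$n_streamlined, b)
    expect_true(m$r >= 0 && m$r <= 1)
  }
})

test_that("copA* allele frequency agrees with the coverage-implied fraction", {
  expect_equal(copA_consistency(estimate_mixture(10, 1), 0.9), 0)
  expect_equal(copA_consistency(estimate_mixture(5, 5), 0), 0)

  # clone with 4 streamlined + 1 full copies: allele reads at the
  # backbone-level locus depth should agree within 0.05 nearly always
  hits <- vapply(1:100, function(s) {
    prof <- simulate_coverage(n_full = 1, n_streamlined = 4,
                              chrom_depth = 100, plasmid_length = 20000,
                              deletion = c(5000, 15000), seed = s)
    mix <- estimate_mixture(
      relative_coverage(mean(prof$depth[c(1:4999, 15001:20000)]), 100),
      relative_coverage(mean(prof$depth[5000:15000]), 100))
    counts <- simulate_allele_counts(500, 0.8, seed = s + 1000)
    freq <- counts[["mutant"]] / sum(counts)
    abs(copA_consistency(mix, freq)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("r versus copA* frequency reproduces the -1 slope anticorrelation", {
  set.seed(21)
  n_str <- round(seq(0, 10, length.out = 24))
  panel <- lapply(seq_along(n_str), function(i) {
    prof <- simulate_coverage(n_full = max(1, 10 - n_str[i]),
                              n_streamlined = n_str[i],
                              chrom_depth = 50, seed = 300 + i)
    b <- relative_coverage(region_mean(prof, "backbone"), 50)
    a <- relative_coverage(region_mean(prof, "AMR"), 50)
    mix <- estimate_mixture(b, a)
    cnt <- simulate_allele_counts(400, mix$streamlined_fraction,
                                  seed = 600 + i)
    data.frame(r = mix$r, freq = cnt[["mutant"]] / sum(cnt))
  })
  panel <- do.call(rbind, panel)
  fit <- stats::lm(r ~ freq, data = panel)
  expect_equal(unname(coef(fit))[2], -1, tolerance = 0.08)
  expect_equal(unname(coef(fit))[1], 1, tolerance = 0.05)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("the deletion caller recovers a clean step exactly and rejects uniform", {
  d <- rep(10, 99378); d[5700:41300] <- 1
  call <- detect_deletion(coverage_profile(d))
  expect_identical(call$start, 5700L)
  expect_identical(call$end, 41300L)
  expect_identical(call$length, 35601L)
  expect_equal(call$length / 1000, 35.6, tolerance = 0.002)

  expect_null(detect_deletion(coverage_profile(rep(8, 99378))))
  set.seed(9)
  expect_null(detect_deletion(coverage_profile(rpois(99378, 200))))
  expect_error(detect_deletion(coverage_profile(rep(0, 9999))), "degenerate")
  expect_error(detect_deletion(coverage_profile(rep(1, 100))), "shorter")
})

test_that("deletion boundaries under Poisson noise stay within the window", {
  window <- 501L
  ok <- vapply(1:20, function(s) {
    prof <- simulate_coverage(n_full = 1, n_streamlined = 9,
                              chrom_depth = 50, seed = 40 + s)
    call <- detect_deletion(prof, window = window)
    !is.null(call) && abs(call$start - 5700) <= window &&
      abs(call$end - 41300) <= window
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("deletion calls are invariant to global depth scaling", {
  prof <- simulate_coverage(n_full = 1, n_streamlined = 9, chrom_depth = 50,
                            seed = 77)
  c1 <- detect_deletion(prof)
  scaled <- coverage_profile(prof$depth * 7, chrom_mean = 350)
  c2 <- detect_deletion(scaled)
  expect_identical(c(c1$start, c1$end), c(c2$start, c2$end))
})
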