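# shared fixtures for the model tests

standard_params <- function(...) model_params(...)

# brute-force replacement-time oracle: dense fixed-grid integration and
# linear interpolation of the first threshold crossing, independent of the
# integrator's root finder
replacement_scan <- function(params, criterion = replacement_criterion(),
                             t_max = 1e4, n = 20001L) {
  tr <- simulate_competition(params, t_max = t_max,
                             times = seq(0, t_max, length.out = n),
                             criterion = NULL)
  wt <- rowSums(tr[, criterion$compartments, drop = FALSE])
  gap <- if (criterion$mode == "absolute_density") {
    wt - criterion$threshold
  } else {
    tot <- tr$N0 + tr$NW + tr$NM + tr$NWM
    wt / tot - criterion$threshold
  }
  i <- which(gap <= 0)[1L]
  if (is.na(i)) return(Inf)
  if (i == 1L) return(tr$time[1L])
  # linear interpolation between the bracketing grid points
  t0 <- tr$time[i - 1L]; t1 <- tr$time[i]
  g0 <- gap[i - 1L]; g1 <- gap[i]
  t0 + g0 / (g0 - g1) * (t1 - t0)
}

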