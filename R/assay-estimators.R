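#' Cell density from a colony count
#'
#' Converts a plate count back to a culture density:
#' `colonies * dilution / volume` cells per mL. A plate with zero colonies
#' yields the detection-threshold density obtained by assuming half a
#' colony was observed, flagged as censored (the true density lies at or
#' below it).
#'
#' @param colonies Non-negative colony count.
#' @param dilution Dilution factor of the plated sample (>= 1).
#' @param volume Plated volume in mL (> 0).
#' @return Density in cells per mL, with attribute `censored` (logical).
#' @export
density_from_plate <- function(colonies, dilution = 1, volume = 0.1) {
  if (!is.finite(colonies) || colonies < 0) stop("'colonies' must be >= 0")
  if (dilution < 1) stop("'dilution' must be >= 1")
  if (volume <= 0) stop("'volume' must be > 0")
  censored <- colonies == 0
  eff <- if (censored) 0.5 else colonies
  structure(eff * dilution / volume, censored = censored)
}

#' Conjugative transfer efficiency
#'
#' The endpoint estimator `gamma = T / (D * R * t)` (mL per cell per
#' hour), where `T`, `D` and `R` are the transconjugant, donor and
#' recipient densities (cells/mL) measured at the end of the assay and `t`
#' is the incubation time in hours. When no transconjugant colony was
#' detected, `T` should be the 0.5-colony threshold density (see
#' [density_from_plate()]); the resulting efficiency is an upper bound and
#' is flagged censored.
#'
#' The estimator ignores transconjugant growth and re-conjugation during
#' the assay, which is why it is applied to short (~1 h) assays; the bias
#' this induces can be quantified against [simulate_conjugation()].
#'
#' @param T_density Transconjugant density (cells/mL), possibly carrying a
#'   `censored` attribute from [density_from_plate()].
#' @param D_density,R_density Donor and recipient densities (cells/mL,
#'   > 0), measured at the endpoint.
#' @param t Incubation time in hours (> 0).
#' @param censored Logical; overrides the `censored` attribute of
#'   `T_density` when given.
#' @return A list of class `transfer_efficiency`: `gamma` (mL/cell/h) and
#'   `censored`.
#' @export
transfer_efficiency <- function(T_density, D_density, R_density, t = 1,
                                censored = NULL) {
  if (D_density <= 0 || R_density <= 0) stop("'D' and 'R' must be > 0")
  if (t <= 0) stop("'t' must be > 0")
  if (T_density < 0) stop("'T' must be >= 0")
  if (is.null(censored))
    censored <- isTRUE(attr(T_density, "censored"))
  structure(list(gamma = as.numeric(T_density) /
                   (as.numeric(D_density) * as.numeric(R_density) * t),
                 censored = censored),
            class = "transfer_efficiency")
}

#' @export
print.transfer_efficiency <- function(x, ...) {
  cat(sprintf("Transfer efficiency gamma = %.3g mL/cell/h%s\n", x$gamma,
              if (x$censored) " (censored: upper bound)" else ""))
  invisible(x)
}

#' Maximal growth rate from an OD curve by sliding log-linear windows
#'
#' Blank-subtracts the readings, drops points at or below the positivity
#' floor, and fits ordinary least squares of `log(OD)` on time over every
#' window of `h` consecutive retained readings whose times lie within
#' `[fit_start, fit_end]` hours. The maximal fitted slope is returned as
#' the maximal growth rate, together with its window and fit diagnostics.
#' Windows are contiguous in retained points only; windows interrupted by
#' excluded readings are not formed.
#'
#' @param times Reading times in hours (increasing).
#' @param od Optical-density readings (same length).
#' @param blank Blank value subtracted before the log transform.
#' @param fit_start,fit_end Fit range in hours post-inoculation (defaults
#'   2 and 10).
#' @param h Window size in consecutive readings (default 8).
#' @param floor Positivity floor: readings with `od - blank <= floor` are
#'   excluded (default `1e-4`).
#' @return A list of class `growth_rate_estimate`: `mu_max` (per hour),
#'   `window_start`, `window_end` (hours), `slope_se`, `r_squared`,
#'   `n_windows`.
#' @export
max_growth_rate <- function(times, od, blank = 0,
                            fit_start = 2, fit_end = 10, h = 8L,
                            floor = 1e-4) {
  if (length(times) != length(od)) stop("'times' and 'od' lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be increasing")
  if (any(!is.finite(od))) stop("readings must be finite")
  h <- as.integer(h)
  if (h < 3L) stop("'h' must be at least 3 readings")

  keep <- times >= fit_start & times <= fit_end & (od - blank) > floor
  if (sum(keep) < h)
    stop("fewer than h = ", h, " usable readings in [", fit_start, ", ",
         fit_end, "] h")
  # indices of retained points, grouped into runs unbroken by exclusions
  idx <- which(keep)
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  best <- NULL
  n_windows <- 0L
  for (run in split(idx, run_id)) {
    if (length(run) < h) next
    tt <- times[run]; yy <- log(od[run] - blank)
    for (s in seq_len(length(run) - h + 1L)) {
      w <- s:(s + h - 1L)
      x <- tt[w]; y <- yy[w]
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      slope <- sum(xc * y) / sxx
      n_windows <- n_windows + 1L
      if (is.null(best) || slope > best$slope) {
        res <- y - mean(y) - slope * xc
        se <- sqrt(sum(res^2) / (h - 2L) / sxx)
        tss <- sum((y - mean(y))^2)
        best <- list(slope = slope, se = se,
                     r2 = if (tss > 0) 1 - sum(res^2) / tss else 1,
                     t0 = x[1L], t1 = x[h])
      }
    }
  }
  structure(list(mu_max = best$slope, window_start = best$t0,
                 window_end = best$t1, slope_se = best$se,
                 r_squared = best$r2, n_windows = n_windows),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "mu_max = %.4f / h (window %.2f-%.2f h, se %.2g, R^2 %.3f, %d windows)\n",
    x$mu_max, x$window_start, x$window_end, x$slope_se, x$r_squared,
    x$n_windows))
  invisible(x)
}

#' Marker-carriage proportions from paired plate counts
#'
#' Estimates the fraction of marker-carrying (e.g. antibiotic-resistant)
#' cells at each timepoint as the ratio of the selective-plate density to
#' the nonselective-plate density, capped at 1. When colony counts are
#' supplied, an exact confidence interval is attached: selective and
#' nonselective counts are independent Poisson, so conditional on their
#' sum the selective count is binomial with success probability
#' `f / (1 + f)`; the Clopper-Pearson interval on that probability is
#' transformed back to the fraction scale (and capped at 1).
#'
#' A timepoint whose selective density is censored (zero colonies) keeps
#' its threshold-based fraction and is flagged, and the flag propagates:
#' the returned table carries `any_censored` as an attribute.
#'
#' @param selective Vector of selective-plate densities (cells/mL);
#'   elements may carry a `censored` attribute or be accompanied by
#'   `censored`.
#' @param nonselective Vector of nonselective-plate densities (> 0).
#' @param colonies_sel,colonies_nonsel Optional colony counts behind the
#'   densities, for the exact intervals.
#' @param censored Optional logical vector flagging censored selective
#'   densities.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with columns `fraction`, `lower`, `upper` (NA when
#'   counts are unavailable) and `censored`; attribute `any_censored`.
#' @export
proportion_timeseries <- function(selective, nonselective,
                                  colonies_sel = NULL, colonies_nonsel = NULL,
                                  censored = NULL, conf_level = 0.95) {
  n <- length(selective)
  if (length(nonselective) != n) stop("input lengths differ")
  if (any(nonselective <= 0)) stop("nonselective densities must be > 0")
  if (is.null(censored)) censored <- rep(FALSE, n)
  fraction <- pmin(1, as.numeric(selective) / as.numeric(nonselective))
  lower <- upper <- rep(NA_real_, n)
  if (!is.null(colonies_sel) && !is.null(colonies_nonsel)) {
    for (i in seq_len(n)) {
      tot <- colonies_sel[i] + colonies_nonsel[i]
      if (tot == 0) next
      ci <- stats::binom.test(colonies_sel[i], tot,
                              conf.level = conf_level)$conf.int
      # p = f / (1 + f)  =>  f = p / (1 - p)
      lower[i] <- min(1, ci[1L] / (1 - ci[1L]))
      upper[i] <- min(1, if (ci[2L] >= 1) Inf else ci[2L] / (1 - ci[2L]))
    }
  }
  out <- data.frame(fraction = fraction, lower = lower, upper = upper,
                    censored = censored)
  attr(out, "any_censored") <- any(censored)
  out
}
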