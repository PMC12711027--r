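#' Replacement criterion for plasmid competition
#'
#' Defines when the mutant plasmid is considered to have replaced the
#' wildtype: the wildtype-carrying population falling below a threshold,
#' measured either as an absolute density (0.01 cells per unit volume by
#' default) or as a relative frequency of the total population (1% by
#' default for the frequency mode). Which compartments count as
#' wildtype-carrying is configurable; the default counts cells still
#' carrying the wildtype plasmid, i.e. `NW + NWM`.
#'
#' @param mode `"absolute_density"` or `"relative_frequency"`.
#' @param threshold Positive threshold; a density in the first mode, a
#'   frequency in `(0, 1)` in the second.
#' @param compartments Character vector of compartments counted as
#'   wildtype-carrying; `c("NW", "NWM")` (default) or `"NW"`.
#' @return An object of class `replacement_criterion`.
#' @export
replacement_criterion <- function(mode = c("absolute_density",
                                           "relative_frequency"),
                                  threshold = 0.01,
                                  compartments = c("NW", "NWM")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number")
  if (mode == "relative_frequency" && threshold >= 1)
    stop("a frequency threshold must be < 1")
  if (!all(compartments %in% c("NW", "NWM")) || length(compartments) < 1L)
    stop("'compartments' must be a subset of c(\"NW\", \"NWM\")")
  structure(list(mode = mode, threshold = threshold,
                 compartments = compartments),
            class = "replacement_criterion")
}

# signed distance to the replacement threshold; positive while the wildtype
# is above it
criterion_gap <- function(y, criterion) {
  wt <- 0
  if ("NW" %in% criterion$compartments) wt <- wt + y[2L]
  if ("NWM" %in% criterion$compartments) wt <- wt + y[4L]
  if (criterion$mode == "absolute_density") return(wt - criterion$threshold)
  tot <- y[1L] + y[2L] + y[3L] + y[4L]
  if (tot <= 0) return(-criterion$threshold)
  wt / tot - criterion$threshold
}

#' Integrate the plasmid competition model
#'
#' Numerically integrates [competition_derivs()] with `deSolve`'s
#' stiffness-switching `lsodar` method (adaptive step, `rtol = 1e-8`,
#' `atol = 1e-10` by default). When a [replacement_criterion()] is
#' supplied, the threshold crossing is located by the integrator's root
#' finder on dense output, so the recorded crossing time does not depend on
#' the requested output grid.
#'
#' Small negative excursions (within `10 * atol` of zero) are clipped to 0;
#' anything beyond that aborts with an error, as it indicates an integrator
#' failure rather than roundoff.
#'
#' @param params A [model_params()] object.
#' @param initial A [population_state()]; defaults to the standard initial
#'   condition ([standard_initial_state()]).
#' @param t_max End time (> 0).
#' @param times Output times; defaults to 201 equally spaced points in
#'   `[0, t_max]`. Integration accuracy does not depend on this grid.
#' @param criterion Optional [replacement_criterion()]; if supplied,
#'   integration stops at the first crossing.
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param coinfection_displacement Passed to [competition_derivs()].
#' @return A `plasmid_trajectory`: a data frame with columns `time`, `N0`,
#'   `NW`, `NM`, `NWM` and attributes `params`, `criterion`, `event_time`
#'   (`NA` if no criterion or no crossing), `replaced`, `t_max`, `rtol`,
#'   `atol`.
#' @export
simulate_competition <- function(params,
                                 initial = standard_initial_state(params),
                                 t_max = 1e3,
                                 times = NULL,
                                 criterion = NULL,
                                 rtol = 1e-8, atol = 1e-10,
                                 coinfection_displacement = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max <= 0)
    stop("'t_max' must be a single positive time")
  y0 <- as.numeric(initial[c("N0", "NW", "NM", "NWM")])
  if (any(y0 < 0) || any(!is.finite(y0)))
    stop("initial state must be finite and non-negative")
  if (is.null(times)) times <- seq(0, t_max, length.out = 201L)
  if (is.unsorted(times, strictly = TRUE) || times[1L] < 0 ||
      times[length(times)] > t_max)
    stop("'times' must be strictly increasing within [0, t_max]")

  rhs <- function(t, y, parms) list(competition_rhs(y, parms,
                                                    coinfection_displacement))
  rootfun <- if (!is.null(criterion)) {
    stopifnot(inherits(criterion, "replacement_criterion"))
    function(t, y, parms) criterion_gap(y, criterion)
  } else NULL

  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = params,
                      method = "lsodar", rtol = rtol, atol = atol,
                      rootfunc = rootfun)
  istate <- attr(out, "istate")[1L]
  if (!is.null(istate) && istate < 0)
    stop("integration failed (lsodar istate = ", istate, ")")

  states <- out[, -1L, drop = FALSE]
  if (min(states) < -10 * atol)
    stop("negative densities beyond integrator tolerance (min = ",
         format(min(states)), ")")
  states[states < 0] <- 0

  troot <- attr(out, "troot")
  event_time <- if (!is.null(criterion) && length(troot) > 0L)
    troot[1L] else NA_real_

  traj <- data.frame(time = out[, 1L], N0 = states[, 1L], NW = states[, 2L],
                     NM = states[, 3L], NWM = states[, 4L])
  structure(traj,
            class = c("plasmid_trajectory", "data.frame"),
            params = params, criterion = criterion,
            event_time = event_time,
            replaced = is.finite(event_time),
            t_max = t_max, rtol = rtol, atol = atol)
}

#' Time for the mutant plasmid to replace the wildtype
#'
#' Starts the model from the wildtype single-plasmid equilibrium plus a
#' small co-infected inoculum and integrates until the wildtype-carrying
#' population crosses the replacement threshold. Runs that never cross
#' before `t_max` return `Inf` (a genuine "no replacement" sentinel,
#' distinct from a crossing at exactly `t_max`).
#'
#' @param params A [model_params()] object.
#' @param criterion A [replacement_criterion()].
#' @param t_max Censoring horizon; default `1e5` time units, far beyond all
#'   finite replacement times at the standard parameters.
#' @param initial Initial state; default [standard_initial_state()].
#' @param rtol,atol Integrator tolerances.
#' @param coinfection_displacement Passed to [simulate_competition()].
#' @return A list of class `replacement_result`: `time` (finite crossing
#'   time, or `Inf`), `replaced` (logical), `t_max`, `criterion`.
#' @export
replacement_time <- function(params,
                             criterion = replacement_criterion(),
                             t_max = 1e5,
                             initial = standard_initial_state(params),
                             rtol = 1e-8, atol = 1e-10,
                             coinfection_displacement = TRUE) {
  y0 <- as.numeric(initial[c("N0", "NW", "NM", "NWM")])
  if (criterion_gap(y0, criterion) <= 0)
    return(structure(list(time = 0, replaced = TRUE, t_max = t_max,
                          criterion = criterion),
                     class = "replacement_result"))
  traj <- simulate_competition(params, initial = initial, t_max = t_max,
                               times = c(0, t_max), criterion = criterion,
                               rtol = rtol, atol = atol,
                               coinfection_displacement =
                                 coinfection_displacement)
  et <- attr(traj, "event_time")
  structure(list(time = if (is.finite(et)) et else Inf,
                 replaced = is.finite(et),
                 t_max = t_max, criterion = criterion),
            class = "replacement_result")
}

#' @export
print.replacement_result <- function(x, ...) {
  if (x$replaced)
    cat(sprintf("Replacement at t = %.6g (%s threshold %g)\n",
                x$time, x$criterion$mode, x$criterion$threshold))
  else
    cat(sprintf("No replacement within t_max = %g\n", x$t_max))
  invisible(x)
}
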