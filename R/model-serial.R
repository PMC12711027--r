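#' Serial-transfer simulation with optional immigration
#'
#' Extends the continuous competition model to a daily batch regime
#' mirroring serial-passage experiments: within-day continuous dynamics,
#' then an instantaneous dilution (100-fold by default) into fresh medium,
#' optionally mixing the diluted residents with plasmid-free immigrant
#' cells. With immigrant ratio `r`, the new inoculum is composed of
#' `1/(1 + r)` parts diluted resident culture and `r/(1 + r)` parts
#' plasmid-free cells at the same total density (a 95:1
#' immigrant:resident mix corresponds to `immigrant_ratio = 95`).
#'
#' @param params A [model_params()] object (use `epsilon = 0`; immigration
#'   is modelled discretely here).
#' @param initial A [population_state()] describing the day-0 inoculum,
#'   e.g. 1% wildtype-carrying, 1% mutant-carrying and 98% plasmid-free
#'   cells of the equilibrium density.
#' @param n_days Number of batches.
#' @param day_length Duration of one batch in model time units (default 24).
#' @param dilution_factor Total dilution applied between batches (> 1).
#' @param immigrant_ratio Parts of plasmid-free immigrant culture mixed per
#'   part of diluted resident culture at each passage (0 = none).
#' @param times_per_day Output points within each batch.
#' @param rtol,atol Integrator tolerances.
#' @return A list of class `serial_transfer`: `daily` (data frame of
#'   end-of-batch states, one row per day with columns `day`, `N0`, `NW`,
#'   `NM`, `NWM`), `segments` (data frame of the continuous trajectories
#'   with columns `day`, `time`, and the compartments; `time` is global),
#'   plus the settings used.
#' @export
simulate_serial_transfer <- function(params, initial,
                                     n_days = 8,
                                     day_length = 24,
                                     dilution_factor = 100,
                                     immigrant_ratio = 0,
                                     times_per_day = 25L,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  if (dilution_factor <= 1) stop("'dilution_factor' must be > 1")
  if (immigrant_ratio < 0) stop("'immigrant_ratio' must be >= 0")
  if (n_days < 1L) stop("'n_days' must be >= 1")

  state <- population_state(N0 = initial[["N0"]], NW = initial[["NW"]],
                            NM = initial[["NM"]], NWM = initial[["NWM"]])
  daily <- vector("list", n_days)
  segs <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    traj <- simulate_competition(params, initial = state, t_max = day_length,
                                 times = seq(0, day_length,
                                             length.out = times_per_day),
                                 rtol = rtol, atol = atol)
    segs[[d]] <- data.frame(day = d, time = (d - 1) * day_length + traj$time,
                            traj[, c("N0", "NW", "NM", "NWM")])
    end <- unlist(traj[nrow(traj), c("N0", "NW", "NM", "NWM")])
    daily[[d]] <- data.frame(day = d, t(end))
    # passage: dilute, then mix with plasmid-free immigrants at equal density
    diluted <- end / dilution_factor
    if (immigrant_ratio > 0) {
      w_res <- 1 / (1 + immigrant_ratio)
      immigrants <- c(N0 = sum(diluted), NW = 0, NM = 0, NWM = 0)
      diluted <- w_res * diluted + (1 - w_res) * immigrants
    }
    state <- population_state(N0 = diluted[["N0"]], NW = diluted[["NW"]],
                              NM = diluted[["NM"]], NWM = diluted[["NWM"]])
  }
  structure(list(daily = do.call(rbind, daily),
                 segments = do.call(rbind, segs),
                 params = params, day_length = day_length,
                 dilution_factor = dilution_factor,
                 immigrant_ratio = immigrant_ratio),
            class = "serial_transfer")
}

#' @export
print.serial_transfer <- function(x, ...) {
  cat(sprintf(
    "Serial transfer: %d days x %g time units, %g-fold dilution, %s\n",
    nrow(x$daily), x$day_length, x$dilution_factor,
    if (x$immigrant_ratio > 0)
      sprintf("%g:1 immigrant mix", x$immigrant_ratio) else "no immigration"))
  print(utils::head(x$daily, 3L))
  invisible(x)
}
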