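#' Replacement-time sweep over transmission advantages
#'
#' Computes the replacement time on a grid of horizontal (`a_H`) and
#' vertical (`a_V`) transmission advantages, holding all other parameters
#' at `base`. For each cell, `beta_M = a_H * beta_W` and `s_W = a_V * s_M`.
#' Cells whose implied `s_W + s_M` exceeds 1 are invalid (the loss
#' probabilities are no longer probabilities) and recorded as `NA`.
#'
#' @param aH_grid,aV_grid Non-empty vectors of positive advantage values.
#' @param base A [model_params()] object supplying the fixed parameters.
#' @param criterion A [replacement_criterion()].
#' @param t_max Censoring horizon per cell.
#' @param rtol,atol Integrator tolerances.
#' @return A `plasmid_sweep` object: list with `axes` (named list of the two
#'   grids), `times` (matrix, rows = first axis; `Inf` = no replacement
#'   before `t_max`, `NA` = invalid cell), `t_max`, `criterion`, `base`.
#' @export
sweep_advantages <- function(aH_grid, aV_grid, base = model_params(),
                             criterion = replacement_criterion(),
                             t_max = 1e5, rtol = 1e-8, atol = 1e-10) {
  check_grid(aH_grid, "aH_grid"); check_grid(aV_grid, "aV_grid")
  times <- matrix(NA_real_, length(aH_grid), length(aV_grid),
                  dimnames = list(format(aH_grid), format(aV_grid)))
  for (i in seq_along(aH_grid)) {
    for (j in seq_along(aV_grid)) {
      if (aV_grid[j] * base$s_M + base$s_M > 1) next # invalid: s_W + s_M > 1
      p <- with_advantages(base, a_H = aH_grid[i], a_V = aV_grid[j])
      times[i, j] <- replacement_time(p, criterion, t_max,
                                      rtol = rtol, atol = atol)$time
    }
  }
  new_sweep(list(a_H = aH_grid, a_V = aV_grid), times, t_max, criterion, base)
}

#' Replacement-time sweep over horizontal advantage and host influx
#'
#' As [sweep_advantages()], but the second axis is the influx rate
#' `epsilon` of plasmid-free cells; the vertical advantage is fixed at 1
#' (`s_W = s_M`).
#'
#' @param aH_grid Vector of horizontal advantages.
#' @param epsilon_grid Vector of influx rates (>= 0).
#' @inheritParams sweep_advantages
#' @return A `plasmid_sweep` with axes `a_H` and `epsilon`.
#' @export
sweep_influx <- function(aH_grid, epsilon_grid, base = model_params(),
                         criterion = replacement_criterion(),
                         t_max = 1e5, rtol = 1e-8, atol = 1e-10) {
  check_grid(aH_grid, "aH_grid")
  if (length(epsilon_grid) < 1L || any(!is.finite(epsilon_grid)) ||
      any(epsilon_grid < 0))
    stop("'epsilon_grid' must be non-empty, finite and >= 0")
  times <- matrix(NA_real_, length(aH_grid), length(epsilon_grid),
                  dimnames = list(format(aH_grid), format(epsilon_grid)))
  for (i in seq_along(aH_grid)) {
    for (j in seq_along(epsilon_grid)) {
      p <- model_params(rho = base$rho, c = base$c, gamma = base$gamma,
                        K = base$K, beta_W = base$beta_W,
                        beta_M = aH_grid[i] * base$beta_W,
                        s_W = base$s_M, s_M = base$s_M,
                        k = base$k, epsilon = epsilon_grid[j])
      times[i, j] <- replacement_time(p, criterion, t_max,
                                      rtol = rtol, atol = atol)$time
    }
  }
  new_sweep(list(a_H = aH_grid, epsilon = epsilon_grid), times, t_max,
            criterion, base)
}

#' Advantage sweeps at alternative values of one model parameter
#'
#' Repeats [sweep_advantages()] with one of `beta_W`, `s_M` or `k` set to
#' each of the supplied values, leaving the rest of `base` untouched. When
#' `beta_W` is varied, `beta_M` tracks `a_H * beta_W`; when `s_M` is
#' varied, `s_W` tracks `a_V * s_M`. The default criterion here is the
#' relative-frequency one (wildtype below 1% of all cells), the form used
#' for per-parameter comparisons.
#'
#' @param name One of `"beta_W"`, `"s_M"`, `"k"`.
#' @param values Values to assign to the named parameter.
#' @inheritParams sweep_advantages
#' @return A named list of `plasmid_sweep` objects, one per value.
#' @export
sweep_parameter <- function(name = c("beta_W", "s_M", "k"), values,
                            aH_grid, aV_grid, base = model_params(),
                            criterion = replacement_criterion(
                              mode = "relative_frequency", threshold = 0.01),
                            t_max = 1e5, rtol = 1e-8, atol = 1e-10) {
  name <- match.arg(name)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("'values' must be non-empty and finite")
  out <- lapply(values, function(v) {
    b <- unclass(base)
    b[[name]] <- v
    # keep the dependent rate consistent before re-validation
    if (name == "beta_W") b$beta_M <- b$beta_W
    if (name == "s_M") b$s_W <- b$s_M
    b <- do.call(model_params, b)
    sweep_advantages(aH_grid, aV_grid, base = b, criterion = criterion,
                     t_max = t_max, rtol = rtol, atol = atol)
  })
  names(out) <- paste0(name, "=", format(values))
  out
}

check_grid <- function(g, nm) {
  if (length(g) < 1L || any(!is.finite(g)) || any(g <= 0))
    stop("'", nm, "' must be non-empty, finite and positive")
}

new_sweep <- function(axes, times, t_max, criterion, base) {
  stopifnot(identical(dim(times), lengths(axes, use.names = FALSE)))
  stopifnot(all(times[is.finite(times)] <= t_max))
  structure(list(axes = axes, times = times, t_max = t_max,
                 criterion = criterion, base = base),
            class = "plasmid_sweep")
}

#' @export
print.plasmid_sweep <- function(x, ...) {
  cat(sprintf("Replacement-time sweep: %d x %d grid over (%s)\n",
              nrow(x$times), ncol(x$times),
              paste(names(x$axes), collapse = ", ")))
  n_cens <- sum(is.infinite(x$times))
  n_inv <- sum(is.na(x$times))
  cat(sprintf("  finite: %d, no replacement before t_max = %g: %d, invalid: %d\n",
              sum(is.finite(x$times)), x$t_max, n_cens, n_inv))
  invisible(x)
}

#' Long-format view of a sweep
#'
#' @param x A `plasmid_sweep`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with one row per grid cell: the two axis values,
#'   `time` (`NA` both for censored and invalid cells), `censored` (no
#'   replacement before `t_max`) and `invalid` (parameter combination
#'   outside the model's constraints).
#' @export
as.data.frame.plasmid_sweep <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  ax <- expand.grid(x$axes[[1L]], x$axes[[2L]], KEEP.OUT.ATTRS = FALSE)
  names(ax) <- names(x$axes)
  tv <- as.vector(x$times) # column-major matches expand.grid order
  data.frame(ax,
             time = ifelse(is.finite(tv), tv, NA_real_),
             censored = is.infinite(tv) & !is.na(tv),
             invalid = is.na(tv))
}
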