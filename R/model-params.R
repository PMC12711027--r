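#' Parameters of the plasmid competition model
#'
#' Bundles all rate constants of the two-plasmid competition model and
#' validates them. Time units are arbitrary; densities are cells per unit
#' volume. The defaults are the standard parameter set used throughout:
#' `rho = 1`, `c = 0.1`, `gamma = 0.1`, `K = 1`, `beta_W = beta_M = 1`,
#' `s_W = s_M = 0.1`, `k = 0.99`, `epsilon = 0`.
#'
#' @param rho Maximal replication rate (per unit time).
#' @param c Plasmid fitness cost, a dimensionless fraction in `[0, 1)`,
#'   applied to replication of every plasmid-carrying compartment.
#' @param gamma Death rate (per unit time).
#' @param K Carrying capacity (cells per unit volume).
#' @param beta_W,beta_M Conjugation rate constants of the wildtype and
#'   mutant plasmid (volume per cell per unit time).
#' @param s_W,s_M Probabilities that a co-infected cell loses all copies of
#'   the wildtype (resp. mutant) plasmid during one replication, each in
#'   `[0, 1]` with `s_W + s_M <= 1`.
#' @param k Entry-exclusion strength in `[0, 1]`: a plasmid-carrying cell is
#'   `1 - k` times as susceptible to co-infection as a plasmid-free cell.
#' @param epsilon Influx of plasmid-free cells (cells per unit volume per
#'   unit time).
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [with_advantages()] to derive a parameter set from transmission
#'   advantages, [single_plasmid_equilibrium()], [simulate_competition()].
#' @examples
#' p <- model_params()
#' advantages(p) # a_H = beta_M / beta_W, a_V = s_W / s_M
#' @export
model_params <- function(rho = 1, c = 0.1, gamma = 0.1, K = 1,
                         beta_W = 1, beta_M = 1, s_W = 0.1, s_M = 0.1,
                         k = 0.99, epsilon = 0) {
  p <- list(rho = rho, c = c, gamma = gamma, K = K,
            beta_W = beta_W, beta_M = beta_M, s_W = s_W, s_M = s_M,
            k = k, epsilon = epsilon)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  if (any(unlist(p[c("rho", "gamma", "K", "beta_W", "beta_M", "epsilon")]) < 0))
    stop("rates, carrying capacity and influx must be >= 0", call. = FALSE)
  if (p$c < 0 || p$c >= 1) stop("'c' must lie in [0, 1)", call. = FALSE)
  if (p$s_W < 0 || p$s_W > 1 || p$s_M < 0 || p$s_M > 1)
    stop("'s_W' and 's_M' must lie in [0, 1]", call. = FALSE)
  if (p$s_W + p$s_M > 1 + 1e-12)
    stop("segregational loss probabilities must satisfy s_W + s_M <= 1",
         call. = FALSE)
  if (p$k < 0 || p$k > 1) stop("'k' must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Derive a parameter set from transmission advantages
#'
#' The mutant plasmid's advantages are parametrised as a fold-change in the
#' conjugation rate (horizontal, `a_H = beta_M / beta_W`) and in retention
#' during replication (vertical, `a_V = s_W / s_M`). This helper rescales a
#' base parameter set so that `beta_M = a_H * beta_W` and `s_W = a_V * s_M`.
#'
#' @param base A [model_params()] object supplying `beta_W`, `s_M` and all
#'   other rates.
#' @param a_H Horizontal transmission advantage (>= 0).
#' @param a_V Vertical transmission advantage (>= 0). Values with
#'   `a_V * s_M + s_M > 1` violate the loss-probability constraint and are
#'   rejected.
#' @return A `model_params` object.
#' @export
with_advantages <- function(base, a_H = 1, a_V = 1) {
  stopifnot(inherits(base, "model_params"))
  if (!is.finite(a_H) || a_H < 0) stop("'a_H' must be >= 0")
  if (!is.finite(a_V) || a_V < 0) stop("'a_V' must be >= 0")
  model_params(rho = base$rho, c = base$c, gamma = base$gamma, K = base$K,
               beta_W = base$beta_W, beta_M = a_H * base$beta_W,
               s_W = a_V * base$s_M, s_M = base$s_M,
               k = base$k, epsilon = base$epsilon)
}

#' Transmission advantages implied by a parameter set
#'
#' @param p A [model_params()] object.
#' @return Named numeric vector with `a_H = beta_M / beta_W` and
#'   `a_V = s_W / s_M` (`NA` where the denominator is zero).
#' @export
advantages <- function(p) {
  stopifnot(inherits(p, "model_params"))
  c(a_H = if (p$beta_W > 0) p$beta_M / p$beta_W else NA_real_,
    a_V = if (p$s_M > 0) p$s_W / p$s_M else NA_real_)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Plasmid competition model parameters\n")
  cat(sprintf("  rho = %g, c = %g, gamma = %g, K = %g\n",
              x$rho, x$c, x$gamma, x$K))
  cat(sprintf("  beta_W = %g, beta_M = %g (a_H = %s)\n",
              x$beta_W, x$beta_M, format(advantages(x)[["a_H"]])))
  cat(sprintf("  s_W = %g, s_M = %g (a_V = %s)\n",
              x$s_W, x$s_M, format(advantages(x)[["a_V"]])))
  cat(sprintf("  k = %g, epsilon = %g\n", x$k, x$epsilon))
  invisible(x)
}

#' Population state of the competition model
#'
#' Densities (cells per unit volume) of the four compartments: plasmid-free
#' cells (`N0`), cells carrying only the wildtype (`NW`) or only the mutant
#' (`NM`) plasmid, and co-infected cells (`NWM`).
#'
#' @param N0,NW,NM,NWM Non-negative finite densities.
#' @return Named numeric vector of class `population_state`.
#' @export
population_state <- function(N0 = 0, NW = 0, NM = 0, NWM = 0) {
  y <- c(N0 = N0, NW = NW, NM = NM, NWM = NWM)
  if (!all(is.finite(y))) stop("densities must be finite")
  if (any(y < 0)) stop("densities must be >= 0")
  structure(y, class = c("population_state", "numeric"))
}

#' Total cell density of a state
#' @param state A [population_state()] (or any 4-vector N0, NW, NM, NWM).
#' @return Total density `N0 + NW + NM + NWM`.
#' @export
total_density <- function(state) {
  sum(state[c("N0", "NW", "NM", "NWM")])
}
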