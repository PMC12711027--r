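#' Force of infection exerted by each plasmid
#'
#' Each plasmid's per-recipient infection rate is proportional to the
#' density of cells transmitting it: singly infected carriers plus half the
#' co-infected cells (co-infected cells conjugate at the same overall rate
#' as singly infected ones, transmitting each variant with probability 1/2):
#' `lambda_i = beta_i * (N_i + NWM / 2)`.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(lambda_W, lambda_M)` (per unit time).
#' @export
force_of_infection <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(state < 0)) stop("densities must be >= 0")
  half_wm <- state[["NWM"]] / 2
  c(lambda_W = params$beta_W * (state[["NW"]] + half_wm),
    lambda_M = params$beta_M * (state[["NM"]] + half_wm))
}

# Raw right-hand side used by both the exported wrapper and the integrator.
# y is an unnamed numeric 4-vector (N0, NW, NM, NWM); no validation here, as
# adaptive integrators probe trial states freely.
competition_rhs <- function(y, p, coinfection_displacement = TRUE) {
  N0 <- y[1L]; NW <- y[2L]; NM <- y[3L]; NWM <- y[4L]
  Tt <- N0 + NW + NM + NWM
  g  <- p$rho * (1 - Tt / p$K)          # density-dependent replication term
  gc <- (1 - p$c) * g                   # with plasmid cost
  lamW <- p$beta_W * (NW + NWM / 2)
  lamM <- p$beta_M * (NM + NWM / 2)
  ke <- 1 - p$k

  dN0  <- N0 * (g - p$gamma - lamM - lamW) + p$epsilon
  dNW  <- NW * (gc - p$gamma) + N0 * lamW - ke * NW * lamM +
    NWM * p$s_M * gc
  dNM  <- NM * (gc - p$gamma) + N0 * lamM - ke * NM * lamW +
    NWM * p$s_W * gc
  dNWM <- NWM * ((1 - p$s_W - p$s_M) * gc - p$gamma) +
    ke * (NW * lamM + NM * lamW)

  if (coinfection_displacement) {
    # Conjugation into an already co-infected cell displaces the resident
    # variant with probability 1/2, returning the cell to single carriage
    # of the incoming plasmid. Without these fluxes the co-infected pool
    # regenerates the disadvantaged plasmid indefinitely and weak
    # advantages end in stable coexistence rather than replacement.
    disp_W <- ke * NWM * lamW / 2
    disp_M <- ke * NWM * lamM / 2
    dNW  <- dNW + disp_W
    dNM  <- dNM + disp_M
    dNWM <- dNWM - disp_W - disp_M
  }
  c(dN0, dNW, dNM, dNWM)
}

#' Time derivatives of the competition model
#'
#' Evaluates the right-hand side of the four coupled ODEs. Writing
#' `g = rho (1 - T/K)` for the density-dependent replication term and
#' `lambda_i` for the forces of infection ([force_of_infection()]):
#'
#' \deqn{dN_0/dt = N_0 (g - \gamma - \lambda_M - \lambda_W) + \epsilon}
#' \deqn{dN_W/dt = N_W ((1-c) g - \gamma) + N_0 \lambda_W
#'   - (1-k) N_W \lambda_M + N_{WM} s_M (1-c) g}
#' \deqn{dN_M/dt = N_M ((1-c) g - \gamma) + N_0 \lambda_M
#'   - (1-k) N_M \lambda_W + N_{WM} s_W (1-c) g}
#' \deqn{dN_{WM}/dt = N_{WM} ((1-s_W-s_M)(1-c) g - \gamma)
#'   + (1-k)(N_W \lambda_M + N_M \lambda_W)}
#'
#' By default, conjugation into an already co-infected cell additionally
#' displaces the resident variant with probability 1/2, adding
#' `+(1-k) NWM lambda_i / 2` to `dN_i/dt` for each plasmid and removing
#' the sum from `dNWM/dt`. This displacement is part of the model proper:
#' without it the co-infected compartment acts as a refuge that
#' regenerates the disadvantaged plasmid, and weak transmission
#' advantages lead to stable coexistence instead of replacement (see the
#' methods vignette). Set `coinfection_displacement = FALSE` for the
#' reduced variant without these fluxes.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] object.
#' @param coinfection_displacement Logical; include the
#'   displacement-on-reinfection fluxes (default `TRUE`).
#' @return Named numeric vector of derivatives `(N0, NW, NM, NWM)`.
#' @export
competition_derivs <- function(state, params, coinfection_displacement = TRUE) {
  stopifnot(inherits(params, "model_params"))
  y <- as.numeric(state[c("N0", "NW", "NM", "NWM")])
  if (any(!is.finite(y))) stop("densities must be finite")
  if (any(y < 0)) stop("densities must be >= 0")
  d <- competition_rhs(y, params, coinfection_displacement)
  names(d) <- c("N0", "NW", "NM", "NWM")
  d
}

#' Equilibrium density of a single plasmid
#'
#' With only the wildtype-carrying compartment populated and no influx, the
#' dynamics reduce to logistic growth with cost-discounted replication; the
#' non-trivial stationary density is
#' `N* = K (1 - gamma / ((1 - c) rho))`.
#' For the standard parameters this is 8/9, i.e. 0.89 cells per unit
#' volume, the starting density of all competition simulations.
#'
#' @param params A [model_params()] object.
#' @return The equilibrium density. When `(1 - c) rho <= gamma` the carrying
#'   population cannot persist: returns 0 with attribute `extinct = TRUE`
#'   and a warning.
#' @export
single_plasmid_equilibrium <- function(params) {
  stopifnot(inherits(params, "model_params"))
  net <- (1 - params$c) * params$rho
  if (net <= params$gamma) {
    if (net < params$gamma)
      warning("plasmid-carrying population cannot persist: (1-c)*rho < gamma")
    return(structure(0, extinct = TRUE))
  }
  params$K * (1 - params$gamma / net)
}

#' Standard initial condition for competition runs
#'
#' The wildtype at its single-plasmid equilibrium plus a small inoculum of
#' co-infected cells (`NWM = 0.01` cells per unit volume by default).
#'
#' @param params A [model_params()] object.
#' @param NWM0 Initial co-infected density.
#' @return A [population_state()].
#' @export
standard_initial_state <- function(params, NWM0 = 0.01) {
  population_state(N0 = 0, NW = as.numeric(single_plasmid_equilibrium(params)),
                   NM = 0, NWM = NWM0)
}
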