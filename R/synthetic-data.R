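#' Synthetic per-base coverage for a plasmid mixture
#'
#' Generates the per-base depth profile expected from a clone carrying a
#' mixture of full-length and streamlined (internally deleted) plasmid
#' copies. The expected depth at each base is
#' `chrom_depth * (n_full + n_streamlined)` outside the deletion and
#' `chrom_depth * n_full` inside it; observed depths are drawn per base as
#' Poisson, or negative binomial when `overdispersion > 1` (variance =
#' `overdispersion * mean`). Deletion boundaries are sharp, as for an
#' IS-bounded recombination deletion; use `boundary_blur` to smear them
#' when stress-testing a caller.
#'
#' The defaults describe the study system: a 99,378 bp replicon with the
#' deletion spanning coordinates 5,700-41,300.
#'
#' @param n_full,n_streamlined Copies per chromosome of each molecule
#'   (>= 0).
#' @param chrom_depth Mean chromosome depth (> 0).
#' @param plasmid_length Reference length in bases.
#' @param deletion Length-2 vector, 1-based inclusive deletion interval.
#' @param overdispersion Variance inflation; 1 = pure Poisson.
#' @param boundary_blur Standard deviation (bases) of Gaussian jitter
#'   applied independently to each boundary before drawing depths
#'   (0 = sharp).
#' @param seed Optional integer seed (generation is then deterministic).
#' @return A [coverage_profile()] with `chrom_mean = chrom_depth` and an
#'   attribute `truth` recording the generating values.
#' @export
simulate_coverage <- function(n_full = 1, n_streamlined = 9,
                              chrom_depth = 100,
                              plasmid_length = 99378L,
                              deletion = c(5700L, 41300L),
                              overdispersion = 1,
                              boundary_blur = 0,
                              seed = NULL) {
  if (n_full < 0 || n_streamlined < 0) stop("copy numbers must be >= 0")
  if (chrom_depth <= 0) stop("'chrom_depth' must be > 0")
  if (deletion[1L] < 1 || deletion[2L] > plasmid_length ||
      deletion[1L] > deletion[2L])
    stop("'deletion' must be an interval within the plasmid")
  if (overdispersion < 1) stop("'overdispersion' must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  del <- deletion
  if (boundary_blur > 0)
    del <- round(del + stats::rnorm(2L, 0, boundary_blur))
  del[1L] <- max(1L, del[1L]); del[2L] <- min(plasmid_length, del[2L])

  copies <- rep(n_full + n_streamlined, plasmid_length)
  copies[del[1L]:del[2L]] <- n_full
  mu <- chrom_depth * copies
  depth <- if (overdispersion == 1) {
    stats::rpois(plasmid_length, mu)
  } else {
    size <- mu / (overdispersion - 1)
    stats::rnbinom(plasmid_length, mu = mu, size = pmax(size, 1e-8))
  }
  prof <- coverage_profile(depth, reference = "plasmid_synth",
                           chrom_mean = chrom_depth)
  attr(prof, "truth") <- list(n_full = n_full, n_streamlined = n_streamlined,
                              chrom_depth = chrom_depth, deletion = del,
                              overdispersion = overdispersion)
  prof
}

#' Synthetic allele counts at a backbone locus
#'
#' Draws read counts at a biallelic locus (e.g. `copA*`) from a clone in
#' which a fraction of the plasmid copies carry the derived allele:
#' `mutant ~ Binomial(depth, streamlined_fraction)`.
#'
#' @param depth Total reads covering the locus.
#' @param streamlined_fraction Fraction of copies carrying the derived
#'   allele, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Named integer vector `c(mutant, ancestral)`.
#' @export
simulate_allele_counts <- function(depth, streamlined_fraction, seed = NULL) {
  if (streamlined_fraction < 0 || streamlined_fraction > 1)
    stop("'streamlined_fraction' must lie in [0, 1]")
  if (depth < 0) stop("'depth' must be >= 0")
  depth <- as.integer(depth)
  if (!is.null(seed)) set.seed(seed)
  mutant <- stats::rbinom(1L, size = depth, prob = streamlined_fraction)
  c(mutant = mutant, ancestral = depth - mutant)
}

#' Synthetic mass-action conjugation assay
#'
#' Integrates the mass-action dynamics of a short liquid conjugation
#' assay, `dT/dt = gamma * D * R` (with optional exponential growth of all
#' populations and optional transconjugant re-conjugation
#' `+ gamma_T * T * R`), then plates each population with Poisson colony
#' noise and returns the observed densities alongside the generating
#' truth.
#'
#' @param gamma_true True transfer rate (mL/cell/h).
#' @param D0,R0 Initial donor and recipient densities (cells/mL).
#' @param duration Assay duration in hours.
#' @param growth_rate Exponential growth rate of all populations during
#'   the assay (per hour; 0 = none, the short-assay idealisation).
#' @param gamma_transconjugant Re-conjugation rate from transconjugants
#'   (mL/cell/h; default 0).
#' @param dilution_T,volume_T Plating of the transconjugant population.
#' @param dilution_DR,volume_DR Plating of donors and recipients.
#' @param replicates Number of independently plated replicates.
#' @param seed Optional integer seed.
#' @return A data frame of class `conjugation_assay`, one row per
#'   replicate, with colony counts, derived densities (`D`, `R`, `T_obs`),
#'   a `censored` flag for zero transconjugant plates and `t`; attribute
#'   `truth` holds the generating rate and the exact final densities.
#' @export
simulate_conjugation <- function(gamma_true = 1e-12, D0 = 1e8, R0 = 1e8,
                                 duration = 1, growth_rate = 0,
                                 gamma_transconjugant = 0,
                                 dilution_T = 1, volume_T = 0.1,
                                 dilution_DR = 1e4, volume_DR = 0.1,
                                 replicates = 1L, seed = NULL) {
  if (gamma_true < 0 || D0 <= 0 || R0 <= 0 || duration <= 0)
    stop("rates and densities must be positive")
  if (!is.null(seed)) set.seed(seed)

  rhs <- function(t, y, p) {
    D <- y[1L]; R <- y[2L]; Tr <- y[3L]
    conv <- gamma_true * D * R + gamma_transconjugant * Tr * R
    list(c(growth_rate * D,
           growth_rate * R - conv,
           growth_rate * Tr + conv))
  }
  out <- deSolve::ode(c(D0, R0, 0), c(0, duration), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-6)
  fin <- out[nrow(out), -1L]
  names(fin) <- c("D", "R", "T")

  plate <- function(density, dilution, volume) {
    stats::rpois(1L, density * volume / dilution)
  }
  rows <- lapply(seq_len(replicates), function(i) {
    cT <- plate(fin[["T"]], dilution_T, volume_T)
    cD <- plate(fin[["D"]], dilution_DR, volume_DR)
    cR <- plate(fin[["R"]], dilution_DR, volume_DR)
    dT <- density_from_plate(cT, dilution_T, volume_T)
    data.frame(replicate = i, colonies_T = cT, colonies_D = cD,
               colonies_R = cR,
               T_obs = as.numeric(dT),
               D = as.numeric(density_from_plate(cD, dilution_DR, volume_DR)),
               R = as.numeric(density_from_plate(cR, dilution_DR, volume_DR)),
               censored = attr(dT, "censored"), t = duration)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("conjugation_assay", "data.frame")
  attr(res, "truth") <- list(gamma_true = gamma_true, final = fin,
                             duration = duration, growth_rate = growth_rate)
  res
}

#' Synthetic OD600 growth curve
#'
#' A lagged-logistic optical-density trajectory: no growth until `lag`
#' hours, then logistic growth at rate `mu` towards carrying capacity
#' `K_od` (an infinite `K_od` gives pure exponential growth). Measurement
#' noise is Gaussian and proportional to the signal
#' (`od_obs = od * (1 + N(0, noise_sd))`), the working model for
#' within-range plate-reader error; the blank is added back to every
#' reading.
#'
#' @param mu Maximal growth rate (per hour, > 0).
#' @param lag Lag phase duration (hours).
#' @param K_od Carrying capacity on the OD scale (may be `Inf`).
#' @param od0 Inoculum OD (above blank).
#' @param noise_sd Proportional noise standard deviation (0 = noiseless).
#' @param blank Blank OD added to every reading.
#' @param interval_min Reading interval in minutes (default 5).
#' @param duration_h Total duration in hours (default 24).
#' @param seed Optional integer seed.
#' @return A list of class `growth_curve`: `times` (hours), `od`
#'   (readings including blank), `blank`, and attribute `truth`.
#' @export
simulate_growth_curve <- function(mu = 0.6, lag = 1, K_od = 1, od0 = 0.01,
                                  noise_sd = 0.005, blank = 0,
                                  interval_min = 5, duration_h = 24,
                                  seed = NULL) {
  if (mu <= 0) stop("'mu' must be > 0")
  if (od0 <= 0) stop("'od0' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_h, by = interval_min / 60)
  te <- pmax(0, times - lag)
  od <- if (is.infinite(K_od)) {
    od0 * exp(mu * te)
  } else {
    K_od * od0 / (od0 + (K_od - od0) * exp(-mu * te))
  }
  if (noise_sd > 0)
    od <- od * (1 + stats::rnorm(length(od), 0, noise_sd))
  structure(list(times = times, od = od + blank, blank = blank),
            class = "growth_curve",
            truth = list(mu = mu, lag = lag, K_od = K_od, od0 = od0,
                         noise_sd = noise_sd))
}

#' Daily marker-carriage series from a model trajectory
#'
#' Maps a competition-model trajectory onto the observable a plating assay
#' reports: the fraction of cells carrying the marker-bearing (wildtype)
#' plasmid, `(NW + NWM) / T`, at the sampled times, with optional binomial
#' colony-sampling noise.
#'
#' @param traj A `plasmid_trajectory` from [simulate_competition()].
#' @param at Times at which to sample (must lie within the trajectory);
#'   defaults to the trajectory's own time grid.
#' @param n_colonies Optional number of colonies screened per timepoint;
#'   when given, `observed` is a binomial draw divided by `n_colonies`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `time`, `fraction` and (when sampled)
#'   `observed`.
#' @export
observables_from_trajectory <- function(traj, at = NULL, n_colonies = NULL,
                                        seed = NULL) {
  stopifnot(inherits(traj, "plasmid_trajectory"))
  if (is.null(at)) at <- traj$time
  if (any(at < min(traj$time)) || any(at > max(traj$time)))
    stop("'at' must lie within the trajectory time range")
  if (!is.null(seed)) set.seed(seed)
  comp <- vapply(c("N0", "NW", "NM", "NWM"), function(v)
    stats::approx(traj$time, traj[[v]], xout = at)$y, numeric(length(at)))
  comp <- matrix(comp, nrow = length(at))
  tot <- rowSums(comp)
  fraction <- ifelse(tot > 0, (comp[, 2L] + comp[, 4L]) / tot, 0)
  out <- data.frame(time = at, fraction = fraction)
  if (!is.null(n_colonies)) {
    out$observed <- stats::rbinom(length(at), n_colonies, fraction) /
      n_colonies
  }
  out
}
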