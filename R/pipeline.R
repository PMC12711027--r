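#' Read a simulation scenario file
#'
#' Scenarios are YAML files with up to four blocks: `params` (fields of
#' [model_params()]), `initial` (either the string `"standard"` or the
#' four compartment densities), `criterion` (fields of
#' [replacement_criterion()]) and `t_max`. Missing entries fall back to
#' the standard parameter set, the standard initial condition, the
#' absolute-density criterion and `t_max = 1e5`.
#'
#' @param path Path to the YAML scenario.
#' @return A list with `params`, `initial`, `criterion`, `t_max`.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  params <- do.call(model_params, as.list(sc$params))
  initial <- if (is.null(sc$initial) || identical(sc$initial, "standard")) {
    standard_initial_state(params)
  } else {
    do.call(population_state, as.list(sc$initial))
  }
  criterion <- do.call(replacement_criterion,
                       as.list(sc$criterion)) # NULL -> defaults
  t_max <- if (is.null(sc$t_max)) 1e5 else as.numeric(sc$t_max)
  list(params = params, initial = initial, criterion = criterion,
       t_max = t_max)
}

# 32-bit FNV-1a over the deparsed configuration; enough to tie outputs to
# the settings that produced them
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31 # stay within R's integer range
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full replacement-time sweep suite
#'
#' Orchestrates the three sweep families over one base parameter set — the
#' advantage grid, the influx grid, and the per-parameter grids — and
#' writes each as a long-format CSV plus a JSON metadata sidecar to
#' `out_dir`. All computation is delegated to [sweep_advantages()],
#' [sweep_influx()] and [sweep_parameter()]; the run is deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @param aH_grid,aV_grid Advantage grids.
#' @param epsilon_grid Influx grid for the influx sweep.
#' @param parameter_values Named list giving the alternative values of each
#'   varied parameter, e.g. `list(beta_W = c(0.5, 2), k = c(0.9, 0.999))`.
#' @param base Base [model_params()].
#' @param criterion Criterion for the advantage and influx sweeps (the
#'   per-parameter sweeps use the relative-frequency criterion).
#' @param t_max Censoring horizon.
#' @return Invisibly, a named list of the file paths written.
#' @export
run_model_suite <- function(out_dir,
                            aH_grid = seq(1, 2, length.out = 10L),
                            aV_grid = seq(1, 2, length.out = 10L),
                            epsilon_grid = c(0, 0.05, 0.1),
                            parameter_values = list(beta_W = c(0.5, 2),
                                                    s_M = c(0.05, 0.2),
                                                    k = c(0.9, 0.999)),
                            base = model_params(),
                            criterion = replacement_criterion(),
                            t_max = 1e5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(aH_grid = aH_grid, aV_grid = aV_grid,
              epsilon_grid = epsilon_grid,
              parameter_values = parameter_values,
              base = unclass(base), criterion = unclass(criterion),
              t_max = t_max)

  adv <- sweep_advantages(aH_grid, aV_grid, base, criterion, t_max)
  infl <- sweep_influx(aH_grid, epsilon_grid, base, criterion, t_max)
  pars <- lapply(names(parameter_values), function(nm) {
    sw <- sweep_parameter(nm, parameter_values[[nm]], aH_grid, aV_grid,
                          base = base, t_max = t_max)
    long <- do.call(rbind, lapply(names(sw), function(lbl) {
      d <- as.data.frame(sw[[lbl]])
      d$parameter <- nm
      d$value <- sw[[lbl]]$base[[nm]]
      d
    }))
    rownames(long) <- NULL
    long
  })

  paths <- c(advantage = file.path(out_dir, "advantage_sweep.csv"),
             influx = file.path(out_dir, "influx_sweep.csv"),
             parameter = file.path(out_dir, "parameter_sweeps.csv"),
             metadata = file.path(out_dir, "metadata.json"))
  utils::write.csv(as.data.frame(adv), paths[["advantage"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(infl), paths[["influx"]],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pars), paths[["parameter"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg, config_hash = config_hash(cfg),
         package = "plasmidrace",
         version = as.character(utils::packageVersion("plasmidrace")),
         integrator = list(method = "lsodar", rtol = 1e-8, atol = 1e-10)),
    paths[["metadata"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(as.list(paths))
}

#' Per-clone coverage and mixture report
#'
#' Runs the coverage deconvolution over a set of clones: region means,
#' chromosome-normalised coverages, the full/streamlined mixture estimate,
#' the deletion call, and (when allele frequencies are supplied) the
#' residual between the observed `copA*` frequency and the
#' coverage-implied streamlined fraction.
#'
#' @param profiles A list of [coverage_profile()] objects, or a character
#'   vector of depth-table paths (read with [read_depth_table()]).
#' @param chrom_means Chromosome mean depths, one per clone; defaults to
#'   each profile's own `chrom_mean`.
#' @param regions A [region_set()].
#' @param copA_freqs Optional vector of observed derived-allele
#'   frequencies per clone.
#' @param window,min_length Passed to [detect_deletion()].
#' @return Data frame with one row per clone. With no input, an empty
#'   data frame (with a warning).
#' @export
run_coverage_report <- function(profiles, chrom_means = NULL,
                                regions = region_set(),
                                copA_freqs = NULL,
                                window = 501L, min_length = 5000L) {
  if (length(profiles) == 0L) {
    warning("no clones supplied; returning an empty report")
    return(data.frame(clone = character(), backbone_mean = numeric(),
                      amr_mean = numeric(), backbone_rel = numeric(),
                      amr_rel = numeric(), n_full = numeric(),
                      n_streamlined = numeric(), r = numeric(),
                      streamlined_fraction = numeric(),
                      deletion_start = integer(), deletion_end = integer(),
                      deletion_length = integer(),
                      copA_residual = numeric()))
  }
  if (is.character(profiles)) {
    nms <- basename(profiles)
    profiles <- lapply(profiles, read_depth_table)
  } else {
    nms <- names(profiles)
    if (is.null(nms)) nms <- paste0("clone_", seq_along(profiles))
  }
  rows <- lapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    cm <- if (!is.null(chrom_means)) chrom_means[i] else prof$chrom_mean
    bm <- region_mean(prof, "backbone", regions)
    am <- region_mean(prof, "AMR", regions)
    brel <- relative_coverage(bm, cm)
    arel <- relative_coverage(am, cm)
    mix <- estimate_mixture(brel, arel)
    del <- detect_deletion(prof, window = window, min_length = min_length)
    data.frame(clone = nms[i], backbone_mean = bm, amr_mean = am,
               backbone_rel = brel, amr_rel = arel,
               n_full = mix$n_full, n_streamlined = mix$n_streamlined,
               r = mix$r, streamlined_fraction = mix$streamlined_fraction,
               deletion_start = if (is.null(del)) NA_integer_ else del$start,
               deletion_end = if (is.null(del)) NA_integer_ else del$end,
               deletion_length = if (is.null(del)) NA_integer_ else
                 del$length,
               copA_residual = if (is.null(copA_freqs)) NA_real_ else
                 copA_consistency(mix, copA_freqs[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
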