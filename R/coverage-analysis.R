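#' Mean depth over a named region
#'
#' Arithmetic mean of per-base depth over the union of the region's
#' intervals; each base is counted once.
#'
#' @param profile A [coverage_profile()].
#' @param region Region name present in `regions`, e.g. `"backbone"` or
#'   `"AMR"`.
#' @param regions A [region_set()]; defaults to the R1 backbone/AMR set.
#' @return Mean depth (reads).
#' @export
region_mean <- function(profile, region, regions = region_set()) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(regions, "region_set"))
  if (!region %in% names(regions))
    stop("unknown region '", region, "'")
  ivs <- regions[[region]]
  if (any(ivs$end > profile$length))
    stop("region '", region, "' extends beyond the reference (",
         profile$length, " bp)")
  idx <- unique(unlist(Map(seq.int, ivs$start, ivs$end)))
  if (length(idx) == 0L) stop("region '", region, "' is empty")
  mean(profile$depth[idx])
}

#' Region depth normalised to the chromosome
#'
#' Dividing a region's mean depth by the mean depth of reads mapped to the
#' chromosome converts read counts to copies per chromosome.
#'
#' @param region_mean Mean depth over the region.
#' @param chrom_mean Mean chromosome depth (> 0).
#' @return Copies per chromosome.
#' @export
relative_coverage <- function(region_mean, chrom_mean) {
  if (!is.finite(chrom_mean) || chrom_mean <= 0)
    stop("'chrom_mean' must be a positive finite depth")
  if (region_mean < 0) stop("'region_mean' must be >= 0")
  region_mean / chrom_mean
}

#' Deconvolve full-length and streamlined plasmid copy numbers
#'
#' Under the two-molecule model, a clone carries `n_full` full-length
#' copies (contributing depth over the whole plasmid) and `n_streamlined`
#' copies with the AMR region deleted (contributing depth only over the
#' backbone). Then the AMR-region relative coverage estimates `n_full` and
#' the backbone relative coverage estimates `n_full + n_streamlined`, so
#'
#' * `n_full = amr_rel`,
#' * `n_streamlined = backbone_rel - amr_rel` (floored at 0),
#' * `r = amr_rel / backbone_rel` (capped at 1), the relative frequency of
#'   the AMR region among plasmid molecules,
#' * `streamlined_fraction = 1 - r`, the expected frequency of
#'   streamlined-specific alleles (e.g. a copy-number-up `copA*` allele
#'   carried by the streamlined molecules).
#'
#' When noise puts `amr_rel` above `backbone_rel`, `n_full` is clamped to
#' `backbone_rel` so that `n_full + n_streamlined` always equals the
#' backbone relative coverage.
#'
#' @param backbone_rel Backbone relative coverage (copies per chromosome,
#'   > 0).
#' @param amr_rel AMR-region relative coverage (>= 0).
#' @return A list of class `mixture_estimate` with fields `backbone_rel`,
#'   `amr_rel`, `n_full`, `n_streamlined`, `r`, `streamlined_fraction`.
#' @export
estimate_mixture <- function(backbone_rel, amr_rel) {
  if (!is.finite(backbone_rel) || backbone_rel <= 0)
    stop("'backbone_rel' must be > 0")
  if (!is.finite(amr_rel) || amr_rel < 0)
    stop("'amr_rel' must be >= 0")
  n_full <- min(amr_rel, backbone_rel)
  r <- n_full / backbone_rel
  structure(list(backbone_rel = backbone_rel, amr_rel = amr_rel,
                 n_full = n_full,
                 n_streamlined = backbone_rel - n_full,
                 r = r, streamlined_fraction = 1 - r),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf(
    "Plasmid mixture: %.2f full-length + %.2f streamlined copies/chromosome\n",
    x$n_full, x$n_streamlined))
  cat(sprintf("  AMR relative frequency r = %.3f, streamlined fraction = %.3f\n",
              x$r, x$streamlined_fraction))
  invisible(x)
}

#' Consistency of a coverage mixture with an observed allele frequency
#'
#' Under the two-molecule model, all streamlined copies carry the derived
#' backbone allele (e.g. `copA*`) and all full-length copies are
#' ancestral, so the allele frequency among reads should equal the
#' streamlined fraction. The residual `copA_star_freq -
#' streamlined_fraction` is near zero when the model holds; across clones
#' this is the negative, linear relation between allele frequency and
#' AMR-region relative coverage.
#'
#' @param mixture A [estimate_mixture()] result.
#' @param copA_star_freq Observed derived-allele frequency in `[0, 1]`.
#' @return The residual (signed).
#' @export
copA_consistency <- function(mixture, copA_star_freq) {
  stopifnot(inherits(mixture, "mixture_estimate"))
  if (!is.finite(copA_star_freq) || copA_star_freq < 0 || copA_star_freq > 1)
    stop("'copA_star_freq' must lie in [0, 1]")
  copA_star_freq - mixture$streamlined_fraction
}

#' Call a large deletion from a coverage profile
#'
#' Detects an internal deletion carried by part of the plasmid copies as a
#' long run of depressed depth. The depth is median-smoothed
#' (`stats::runmed`, window `window` bases), a two-level segmentation
#' threshold is placed midway between the upper (backbone) robust level
#' (the median of the smoothed depth) and the lower robust level (the
#' median of the smoothed depth below the midpoint between the backbone
#' level and the profile minimum), and the longest contiguous
#' below-threshold run of at least `min_length` bases is reported. No call
#' is made when the level separation is less than twice the noise scale
#' (median absolute deviation of the smoothed depth outside candidate
#' runs), which rejects uniform profiles.
#'
#' Boundaries are reported where the smoothed depth crosses the threshold;
#' for a clean step they are exact, and under Poisson noise they are
#' accurate to within the smoothing window.
#'
#' @param profile A [coverage_profile()].
#' @param window Median-filter window in bases (odd; default 501).
#' @param min_length Minimum deletion length to report (default 5000
#'   bases).
#' @return A list of class `deletion_call` with fields `start`, `end`,
#'   `length` (= `end - start + 1`), `inside_level`, `outside_level`,
#'   `threshold`, and `all_runs` (data frame of every qualifying run);
#'   or `NULL` when nothing qualifies.
#' @export
detect_deletion <- function(profile, window = 501L, min_length = 5000L) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (window %% 2L == 0L) window <- window + 1L
  if (profile$length <= window)
    stop("profile shorter than the smoothing window")
  if (all(profile$depth == 0)) stop("degenerate profile: all depths are zero")

  sm <- stats::runmed(profile$depth, k = window, endrule = "median")
  hi <- stats::median(sm)
  # lower robust level: median of the smoothed depth below the midpoint
  # between the backbone level and the profile minimum
  lo <- stats::median(sm[sm <= (hi + min(sm)) / 2])
  thr <- (hi + lo) / 2

  below <- sm < thr
  if (!any(below)) return(NULL)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= min_length)
  if (length(cand) == 0L) return(NULL)

  all_runs <- data.frame(start = starts[cand], end = ends[cand],
                         length = runs$lengths[cand])
  best <- which.max(all_runs$length)
  s <- all_runs$start[best]; e <- all_runs$end[best]

  outside <- rep(TRUE, profile$length)
  outside[s:e] <- FALSE
  noise <- stats::mad(sm[outside])
  if ((hi - lo) < 2 * noise) return(NULL)

  structure(list(start = s, end = e, length = e - s + 1L,
                 inside_level = mean(sm[s:e]),
                 outside_level = mean(sm[outside]),
                 threshold = thr, window = window,
                 all_runs = all_runs),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("Deletion call: %d-%d (%.1f kb), depth %.1f inside vs %.1f outside\n",
              x$start, x$end, x$length / 1000, x$inside_level,
              x$outside_level))
  invisible(x)
}
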