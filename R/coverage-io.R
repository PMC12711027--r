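#' Per-base coverage profile of a plasmid reference
#'
#' Holds unique-read sequencing depth at every base of a single replicon
#' (1-based coordinates), together with the mean depth of reads mapped to
#' the chromosome, which serves as the per-copy normaliser.
#'
#' @param depth Numeric vector of per-base depths; position `i` of the
#'   vector is reference coordinate `i`.
#' @param reference Reference name.
#' @param chrom_mean Mean chromosome depth (> 0 required only where
#'   normalisation is requested).
#' @param unique_reads Flag recording whether depths are unique-read only
#'   (not verified; repeat-derived depth inflates region means).
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(depth, reference = "plasmid",
                             chrom_mean = NA_real_, unique_reads = TRUE) {
  if (length(depth) < 1L) stop("'depth' must be non-empty")
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depths must be finite and >= 0")
  structure(list(reference = reference, length = length(depth),
                 depth = as.numeric(depth), chrom_mean = chrom_mean,
                 unique_reads = isTRUE(unique_reads)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("Coverage profile '%s': %d bp, mean depth %.2f",
              x$reference, x$length, mean(x$depth)))
  if (is.finite(x$chrom_mean))
    cat(sprintf(", chromosome mean %.2f", x$chrom_mean))
  cat("\n")
  invisible(x)
}

#' Read a per-base depth table
#'
#' Reads the three-column tab-delimited dialect written by standard depth
#' utilities (`reference  position  depth`, 1-based positions). Positions
#' absent from the table get depth 0, so tables produced without the
#' all-positions flag are handled correctly.
#'
#' @param path Path to the table (no header).
#' @param reference Reference to keep. Required when the file mixes several
#'   references; defaults to the single reference present.
#' @param length Declared reference length. Defaults to the largest
#'   position seen; positions beyond a declared length are an error.
#' @param chrom_mean Optional chromosome mean depth stored on the profile.
#' @return A [coverage_profile()].
#' @export
read_depth_table <- function(path, reference = NULL, length = NULL,
                             chrom_mean = NA_real_) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("ref", "pos", "depth"),
                           colClasses = c("character", "numeric", "numeric"),
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L) stop("no records in depth table '", path, "'")
  refs <- unique(tab$ref)
  if (is.null(reference)) {
    if (length(refs) > 1L)
      stop("depth table contains several references (",
           paste(refs, collapse = ", "), "); pass 'reference'")
    reference <- refs
  }
  tab <- tab[tab$ref == reference, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("reference '", reference, "' not present in depth table")
  if (any(tab$pos != round(tab$pos)) || any(tab$pos < 1))
    stop("positions must be positive integers (1-based)")
  if (any(tab$depth < 0)) stop("depths must be >= 0")
  if (is.null(length)) length <- max(tab$pos)
  if (max(tab$pos) > length)
    stop("positions exceed the declared reference length (", length, ")")
  depth <- numeric(length)
  depth[tab$pos] <- tab$depth
  coverage_profile(depth, reference = reference, chrom_mean = chrom_mean)
}

#' Write a per-base depth table
#'
#' Inverse of [read_depth_table()]: writes the 3-column tab-delimited
#' depth dialect (all positions, including zeros).
#'
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  utils::write.table(
    data.frame(profile$reference, seq_len(profile$length), profile$depth),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Named genomic interval sets on a plasmid reference
#'
#' A region set is a named list of interval tables (columns `start`,
#' `end`, 1-based inclusive). The default regions are those used to
#' deconvolve plasmid R1 coverage: the backbone (coordinates 1-5570 and
#' 41387-99378) and the antimicrobial-resistance (AMR) region (6200-15335
#' and 15950-40664). The short gaps between them contain repeated
#' insertion sequences where unique-read depth is unreliable and are
#' deliberately part of neither region.
#'
#' @param ... Named interval tables: each a data frame or 2-column matrix
#'   of `start`, `end` pairs. With no arguments, returns the default R1
#'   backbone/AMR set.
#' @param reference_length Optional length against which intervals are
#'   validated.
#' @return An object of class `region_set`.
#' @export
region_set <- function(..., reference_length = NULL) {
  regions <- list(...)
  if (length(regions) == 0L) {
    regions <- list(
      backbone = data.frame(start = c(1, 41387), end = c(5570, 99378)),
      AMR = data.frame(start = c(6200, 15950), end = c(15335, 40664)))
  }
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("all regions must be named")
  regions <- lapply(regions, function(r) {
    r <- as.data.frame(r)
    if (ncol(r) < 2L) stop("each region needs 'start' and 'end' columns")
    names(r)[1:2] <- c("start", "end")
    r <- r[, c("start", "end")]
    if (any(r$start < 1) || any(r$end < r$start))
      stop("intervals must satisfy 1 <= start <= end")
    if (!is.null(reference_length) && any(r$end > reference_length))
      stop("intervals exceed the reference length")
    o <- order(r$start)
    r <- r[o, , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
      stop("intervals within a region must not overlap")
    rownames(r) <- NULL
    r
  })
  structure(regions, class = "region_set")
}

#' Read region definitions from a BED file
#'
#' Converts BED's 0-based half-open intervals to the 1-based inclusive
#' coordinates used internally (`start + 1`, `end`). The BED name column
#' (4th) groups intervals into named regions.
#'
#' @param path Path to a 4+ column BED file.
#' @param reference_length Optional validation length.
#' @return A [region_set()].
#' @export
read_bed_regions <- function(path, reference_length = NULL) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(bed) < 4L) stop("BED file must have at least 4 columns (with names)")
  ivs <- split(data.frame(start = bed[[2L]] + 1, end = bed[[3L]]), bed[[4L]])
  do.call(region_set, c(ivs, list(reference_length = reference_length)))
}
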