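#' Per-base signal tracks
#'
#' A `Track` is a named list of per-base numeric vectors, one per
#' chromosome, at 1-bp resolution. All internal genomic coordinates are
#' 0-based, half-open: base `i` of a chromosome is element `i + 1` of its
#' vector.
#'
#' @param signals named list of numeric vectors (one per chromosome).
#' @return An object of class `nslchrom_track`.
#' @export
Track <- function(signals) {
  if (!is.list(signals) || is.null(names(signals)) ||
      any(!nzchar(names(signals))))
    stopf("Track requires a named list of per-chromosome numeric vectors")
  for (nm in names(signals)) {
    v <- signals[[nm]]
    if (!is.numeric(v)) stopf("track for '%s' is not numeric", nm)
    if (any(!is.finite(v))) stopf("track for '%s' has non-finite values", nm)
  }
  structure(signals, class = "nslchrom_track", resolution = 1L)
}

#' @export
print.nslchrom_track <- function(x, ...) {
  cat("<Track>", length(x), "chromosome(s)\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d bp, mean %.4g\n", nm, length(x[[nm]]),
                mean(x[[nm]])))
  invisible(x)
}

#' Genome-wide mean of a track
#' @param track a [Track()].
#' @return Mean signal over all bases of all chromosomes.
#' @export
track_mean <- function(track) {
  tot <- sum(vapply(track, sum, numeric(1)))
  n <- sum(vapply(track, length, numeric(1)))
  tot / n
}

# Extract track values over [start, end) (0-based, half-open).
track_slice <- function(track, chrom, start, end) {
  v <- track[[chrom]]
  if (is.null(v)) stopf("track has no chromosome '%s'", chrom)
  if (start < 0 || end > length(v) || start >= end)
    stopf("interval %s:[%d,%d) outside track bounds", chrom, start, end)
  v[(start + 1):end]
}
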