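# Genomic-interval helpers. All coordinates in the package are 0-based,
# half-open [start, end) (BED dialect); bin ids are 0-based.

#' Interval midpoint
#'
#' Midpoint of a 0-based half-open interval, rounded down to an integer base
#' pair.
#'
#' @param start,end Integer vectors of interval bounds (0-based half-open).
#' @return Integer vector of midpoints.
#' @export
interval_midpoint <- function(start, end) {
  (start + end) %/% 2L
}

#' Map a base-pair position to a matrix bin
#'
#' @param pos Integer vector of positions (0-based).
#' @param resolution Bin size in bp.
#' @return 0-based bin indices.
#' @export
bin_of <- function(pos, resolution) {
  as.integer(pos %/% resolution)
}

#' Convert between 0-based half-open and 1-based closed coordinates
#'
#' The package works in 0-based half-open coordinates throughout; these two
#' functions form the single conversion layer for 1-based dialects.
#' `to_one_based()` followed by `to_zero_based()` is the identity.
#'
#' @param x A data frame with `start` and `end` columns.
#' @return `x` with coordinates shifted to the other convention.
#' @export
to_one_based <- function(x) {
  stopifnot(all(c("start", "end") %in% names(x)))
  x$start <- x$start + 1L
  x
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(x) {
  stopifnot(all(c("start", "end") %in% names(x)))
  x$start <- x$start - 1L
  x
}

# Per-row: does interval in `x` overlap any interval in `y` (same chrom,
# >= 1 bp)? Both are 0-based half-open tibbles with chrom/start/end.
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  out <- rep(FALSE, nrow(x))
  if (is.null(y) || nrow(y) == 0L) return(out)
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    if (!length(yi)) next
    xr <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    yr <- IRanges::IRanges(start = y$start[yi] + 1L, end = y$end[yi])
    out[xi] <- IRanges::overlapsAny(xr, yr)
  }
  out
}
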