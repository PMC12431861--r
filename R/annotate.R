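# Promoter/enhancer definitions, loop-domain lookup and enhancer-flank
# counting.

#' Promoter intervals around transcription start sites
#'
#' @param tss Tibble with `chrom` and `pos` (TSS base, 0-based).
#' @param flank_bp Flank on each side; promoters are
#'   `[pos - flank_bp, pos + flank_bp)`, clipped at 0.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
define_promoters <- function(tss, flank_bp = 500L) {
  if (is.null(tss) || nrow(tss) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  tibble::tibble(
    chrom = tss$chrom,
    start = pmax(0L, as.integer(tss$pos - flank_bp)),
    end = as.integer(tss$pos + flank_bp)
  )
}

#' Annotate peaks as promoter-overlapping
#'
#' A peak is promoter-overlapping when at least one base overlaps a
#' `[tss - flank_bp, tss + flank_bp)` window (the +/- 3 kb convention for
#' peak annotation).
#'
#' @param peaks Peak tibble.
#' @param tss Tibble with `chrom`, `pos`.
#' @param flank_bp Promoter half-width for annotation.
#' @return `peaks` with a logical `promoter` column.
#' @export
annotate_peak_promoter <- function(peaks, tss, flank_bp = 3000L) {
  prom <- define_promoters(tss, flank_bp = flank_bp)
  peaks$promoter <- overlaps_any(peaks, prom)
  peaks
}

#' Active enhancers
#'
#' Open-chromatin (ATAC) peaks that overlap an H3K27ac-enriched region by
#' at least one base and overlap no promoter. Order-independent and
#' idempotent in its inputs.
#'
#' @param open_peaks,acetyl_peaks,promoters Interval tibbles with `chrom`,
#'   `start`, `end`.
#' @return The enhancer subset of `open_peaks`.
#' @export
define_enhancers <- function(open_peaks, acetyl_peaks, promoters) {
  keep <- overlaps_any(open_peaks, acetyl_peaks) &
    !overlaps_any(open_peaks, promoters)
  open_peaks[keep, , drop = FALSE]
}

#' Smallest containing loop domain
#'
#' A loop domain is the interval between the midpoints of a loop's two
#' anchors. For each query point, returns the containing domain with the
#' smallest midpoint span (ties break to the leftmost 5' midpoint), or
#' missing fields when no domain contains the point.
#'
#' @param points Tibble with `chrom`, `pos`.
#' @param loops Loop tibble (see [read_bedpe()]).
#' @return `points` with `domain_start`, `domain_end`, `domain_span`
#'   added.
#' @export
smallest_containing_domain <- function(points, loops) {
  mid5 <- interval_midpoint(loops$start5, loops$end5)
  mid3 <- interval_midpoint(loops$start3, loops$end3)
  span <- mid3 - mid5
  res <- purrr::map(seq_len(nrow(points)), function(k) {
    cand <- which(loops$chrom == points$chrom[k] & mid5 <= points$pos[k] &
                    points$pos[k] <= mid3)
    if (!length(cand)) return(NULL)
    cand <- cand[order(span[cand], mid5[cand])]
    best <- cand[1]
    c(start = mid5[best], end = mid3[best])
  })
  points$domain_start <- purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x[["start"]])
  points$domain_end <- purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x[["end"]])
  points$domain_span <- points$domain_end - points$domain_start
  points
}

#' Count enhancers in loop-domain flanks
#'
#' Counts enhancers overlapping the 500-kb windows immediately outside
#' each domain's two ends - `[domain_start - flank_bp, domain_start)` and
#' `[domain_end, domain_end + flank_bp)` - and sums the two counts. An
#' enhancer overlapping both flanks counts once per flank; enhancers
#' inside the domain body contribute nothing.
#'
#' @param domains Tibble with `chrom`, `domain_start`, `domain_end` (see
#'   [smallest_containing_domain()]).
#' @param enhancers Interval tibble.
#' @param flank_bp Flank width.
#' @return `domains` with an `n_flank_enhancers` column (missing where
#'   the domain is missing).
#' @export
count_flank_enhancers <- function(domains, enhancers, flank_bp = 500000L) {
  count_in <- function(chrom, lo, hi) {
    if (is.na(lo) || hi <= lo) return(NA_integer_)
    sum(enhancers$chrom == chrom & enhancers$start < hi &
          enhancers$end > lo)
  }
  domains$n_flank_enhancers <- purrr::map_int(
    seq_len(nrow(domains)), function(k) {
      if (is.na(domains$domain_start[k])) return(NA_integer_)
      left <- count_in(domains$chrom[k],
                       domains$domain_start[k] - flank_bp,
                       domains$domain_start[k])
      right <- count_in(domains$chrom[k], domains$domain_end[k],
                        domains$domain_end[k] + flank_bp)
      as.integer(left + right)
    })
  domains
}

#' Nearest-neighbour distance between interval sets
#'
#' Midpoint-to-midpoint distance from each query interval to the nearest
#' subject interval on the same chromosome. Subjects identical to the
#' query (same chrom, start, end) are excluded, so a set can be compared
#' against itself; queries with no eligible subject get a missing
#' distance.
#'
#' @param query,subject Interval tibbles with `chrom`, `start`, `end`.
#' @return `query` with a `nearest_dist` column (bp).
#' @export
nearest_distance <- function(query, subject) {
  qm <- interval_midpoint(query$start, query$end)
  sm <- interval_midpoint(subject$start, subject$end)
  query$nearest_dist <- purrr::map_dbl(seq_len(nrow(query)), function(k) {
    keep <- subject$chrom == query$chrom[k] &
      !(subject$start == query$start[k] & subject$end == query$end[k])
    if (!any(keep)) return(NA_real_)
    min(abs(sm[keep] - qm[k]))
  })
  query
}

#' Overlap of two sets from their marginal counts
#'
#' Inclusion-exclusion arithmetic for two gene sets reported only by their
#' sizes and the size of their union (for example, differentially
#' expressed genes called separately in two cell types out of one combined
#' total): the shared count is `n_a + n_b - n_union` and the shared
#' percentage is relative to the union.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param n_union Size of their union.
#' @return A tibble with `shared_count` and `shared_percent`.
#' @export
set_overlap_stats <- function(n_a, n_b, n_union) {
  shared <- n_a + n_b - n_union
  if (shared < 0) stop("marginals exceed the union: counts are inconsistent")
  tibble::tibble(shared_count = as.integer(shared),
                 shared_percent = 100 * shared / n_union)
}
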