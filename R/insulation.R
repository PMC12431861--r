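# Insulation-score track, insulation-peak calling, and per-peak
# differential insulation between two conditions.

square_mean <- function(m, ci, cj, hs) {
  n <- nrow(m)
  ri <- (ci - hs):(ci + hs)
  rj <- (cj - hs):(cj + hs)
  if (ri[1] < 0L || rj[1] < 0L || ri[length(ri)] >= n ||
      rj[length(rj)] >= n) {
    return(NA_real_)
  }
  mean(m[ri + 1L, rj + 1L])
}

#' Insulation-score track
#'
#' For each bin `i`, three `s x s` squares are read off the (by default
#' expected-normalized) matrix: the upstream intra-domain square `U`
#' centered at `(i-d, i-d)`, the downstream square `D` at `(i+d, i+d)`,
#' and the cross square `X` at `(i-d, i+d)` - whose center lies `2d` bins
#' from the diagonal (10 bins with the defaults, at `s = 3`). The
#' insulation score is `IS(i) = log2(((U+D)/2 + eps) / (X + eps))`: a
#' featureless matrix scores ~0 and contact insulators score high. The
#' score is missing within `d + floor(s/2)` bins of the matrix ends and
#' wherever a square touches a masked bin.
#'
#' @param bm A `balanced_matrix`.
#' @param s Square side in bins.
#' @param d Half-offset of the square centers from the diagonal, in bins.
#' @param expected_normalize Divide by the per-distance expected signal
#'   first (see [oe_matrix()]).
#' @param eps Pseudocount.
#' @return An `insulation_track` tibble: `chrom`, `bin`, `start`, `end`,
#'   `score`; parameters kept as attributes.
#' @export
insulation_track <- function(bm, s = 3L, d = 5L, expected_normalize = TRUE,
                             eps = 1e-9) {
  stopifnot(inherits(bm, "balanced_matrix"), s >= 1L, d >= 1L)
  n <- n_bins(bm)
  hs <- s %/% 2L
  m <- if (expected_normalize) oe_matrix(bm) else {
    v <- bm$values
    v[!bm$valid, ] <- NA_real_
    v[, !bm$valid] <- NA_real_
    v
  }
  score <- rep(NA_real_, n)
  if (n >= 2L * d + s) {
    for (i in (d + hs):(n - 1L - d - hs)) {
      u <- square_mean(m, i - d, i - d, hs)
      dn <- square_mean(m, i + d, i + d, hs)
      x <- square_mean(m, i - d, i + d, hs)
      score[i + 1L] <- log2(((u + dn) / 2 + eps) / (x + eps))
    }
  }
  out <- tibble::tibble(
    chrom = bm$chrom,
    bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * bm$resolution,
    end = seq_len(n) * bm$resolution,
    score = score
  )
  attr(out, "s") <- as.integer(s)
  attr(out, "d") <- as.integer(d)
  attr(out, "resolution") <- bm$resolution
  attr(out, "expected_normalize") <- expected_normalize
  class(out) <- c("insulation_track", class(out))
  out
}

#' Insulation peaks
#'
#' Maximal runs of at least `min_run` consecutive bins with insulation
#' score strictly above `threshold`. Missing bins break runs. The reported
#' summit is the bin of maximum score within the run (leftmost on ties).
#'
#' @param track An [insulation_track()].
#' @param threshold Score threshold (strict inequality).
#' @param min_run Minimum run length in bins.
#' @return Tibble with `chrom`, `start_bin`, `end_bin` (inclusive),
#'   `n_bins`, `mean_is`, `summit_bin`.
#' @export
insulation_peaks <- function(track, threshold = 0.75, min_run = 3L) {
  ok <- !is.na(track$score) & track$score > threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  purrr::map_dfr(keep, function(k) {
    rows <- starts[k]:ends[k]
    sc <- track$score[rows]
    tibble::tibble(
      chrom = track$chrom[rows[1]],
      start_bin = track$bin[rows[1]],
      end_bin = track$bin[rows[length(rows)]],
      n_bins = length(rows),
      mean_is = mean(sc),
      summit_bin = track$bin[rows[which.max(sc)]]
    )
  })
}

#' Per-peak differential insulation
#'
#' For each insulation peak, the mean over its bins of
#' `IS_reference - IS_alternate`. Bins missing in either track are
#' excluded from the mean; a peak with no shared defined bin gets a
#' missing `delta_is`.
#'
#' @param peaks Peaks from [insulation_peaks()].
#' @param track_ref,track_alt [insulation_track()]s on the same binning.
#' @return `peaks` with a `delta_is` column.
#' @export
insulation_delta <- function(peaks, track_ref, track_alt) {
  if (nrow(track_ref) != nrow(track_alt) ||
      any(track_ref$bin != track_alt$bin)) {
    stop("tracks are not on the same binning")
  }
  peaks$delta_is <- purrr::map_dbl(seq_len(nrow(peaks)), function(k) {
    rows <- which(track_ref$bin >= peaks$start_bin[k] &
                    track_ref$bin <= peaks$end_bin[k])
    diff <- track_ref$score[rows] - track_alt$score[rows]
    diff <- diff[!is.na(diff)]
    if (length(diff)) mean(diff) else NA_real_
  })
  peaks
}
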