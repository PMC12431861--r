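# Peak-level signal extraction and congruent-change differential calls.

#' Coverage signal at peak summits
#'
#' Summarizes a per-base coverage track around each peak summit, either as
#' the area under the curve over the 200-bp window `summit +/- 100`
#' (`"auc_200bp"`, uncovered bases count 0) or as the mean over the 100-bp
#' window `summit +/- 50` (`"mean_100bp"`, uncovered bases are excluded
#' from the denominator). A peak on a chromosome absent from the track
#' gets a missing value.
#'
#' @param peaks Peak tibble with `chrom` and `summit`.
#' @param track Track tibble (`chrom`, `start`, `end`, `value`), 0-based
#'   half-open, as from [read_bedgraph()].
#' @param mode `"auc_200bp"` or `"mean_100bp"`.
#' @return `peaks` with a `signal` column added.
#' @export
peak_signal <- function(peaks, track, mode = c("auc_200bp", "mean_100bp")) {
  mode <- match.arg(mode)
  half <- if (mode == "auc_200bp") 100L else 50L
  sig <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    win_lo <- peaks$summit[pi] - half
    win_hi <- peaks$summit[pi] + half
    qr <- IRanges::IRanges(start = win_lo + 1L, end = win_hi)
    sr <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    ov <- IRanges::findOverlaps(qr, sr)
    olen <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]))
    val <- track$value[ti][S4Vectors::subjectHits(ov)]
    wsum <- tapply(val * olen, S4Vectors::queryHits(ov), sum)
    cov <- tapply(olen, S4Vectors::queryHits(ov), sum)
    out <- rep(if (mode == "auc_200bp") 0 else NA_real_, length(pi))
    qh <- as.integer(names(wsum))
    if (mode == "auc_200bp") {
      out[qh] <- wsum
    } else {
      out[qh] <- wsum / cov
    }
    sig[pi] <- out
  }
  peaks$signal <- sig
  peaks
}

#' Congruent-change differential peaks
#'
#' Classifies each peak by comparing paired replicate signals between two
#' conditions: replicate `k` of the reference condition against replicate
#' `k` of the alternate. A pair votes `gain` when the alternate signal is
#' at least `(1 + min_change)` times the reference (a reference of zero
#' with positive alternate counts as gain) and `loss` when it is at most
#' `(1 - min_change)` times the reference. A peak is classed `gain` or
#' `loss` only when every pair votes the same way; anything else - and a
#' 25% change in only one replicate in particular - is `unchanged`.
#'
#' @param peaks Peak tibble carrying one signal column per replicate.
#' @param ref_cols,alt_cols Column names of the two conditions' replicate
#'   signals, paired by position; equal lengths required.
#' @param min_change Minimum congruent change fraction (0.25 = 25%).
#' @return `peaks` with `class` (`"gain"`, `"loss"`, `"unchanged"`) and a
#'   `change_frac` list column of per-pair change fractions
#'   `(alt - ref) / ref`.
#' @export
congruent_change_peaks <- function(peaks, ref_cols, alt_cols,
                                   min_change = 0.25) {
  if (length(ref_cols) != length(alt_cols)) {
    stop("unequal replicate counts between conditions")
  }
  if (length(ref_cols) == 0L) stop("at least one replicate pair is required")
  np <- nrow(peaks)
  gain_all <- rep(TRUE, np)
  loss_all <- rep(TRUE, np)
  fracs <- matrix(NA_real_, np, length(ref_cols))
  for (k in seq_along(ref_cols)) {
    ref <- peaks[[ref_cols[k]]]
    alt <- peaks[[alt_cols[k]]]
    gain_k <- alt >= (1 + min_change) * ref & (ref > 0 | alt > 0)
    loss_k <- ref > 0 & alt <= (1 - min_change) * ref
    gain_all <- gain_all & gain_k
    loss_all <- loss_all & loss_k
    fracs[, k] <- (alt - ref) / ref
  }
  peaks$class <- dplyr::case_when(gain_all ~ "gain", loss_all ~ "loss",
                                  TRUE ~ "unchanged")
  peaks$change_frac <- lapply(seq_len(np), function(i) fracs[i, ])
  peaks
}

#' Count CG dinucleotides
#'
#' @param sequences Character vector of DNA sequences (typically 500-bp
#'   summit windows).
#' @return Integer vector of CG occurrence counts.
#' @export
count_cpg <- function(sequences) {
  if (!length(sequences)) return(integer(0))
  as.integer(Biostrings::vcountPattern(
    "CG", Biostrings::DNAStringSet(toupper(sequences))))
}
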