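# PWM scanning with min-max relative scores and summit-window motif
# orientation. Raw score of a window is sum(log(p_base / background_base));
# N positions score as background (contribution 0). The relative score
# rescales between the motif's minimum and maximum attainable raw scores,
# matching the "min.score" percentage convention of PWM hit counting.

pwm_score_matrix <- function(pwm_obj) {
  log(pwm_obj$prob / pwm_obj$background)
}

# Raw scores at every start of `idx` (integer-encoded sequence, NA = N).
pwm_raw_scores <- function(idx, smat) {
  w <- ncol(smat)
  np <- length(idx) - w + 1L
  raw <- numeric(np)
  for (k in seq_len(w)) {
    contrib <- unname(smat[, k])[idx[k:(k + np - 1L)]]
    contrib[is.na(contrib)] <- 0
    raw <- raw + contrib
  }
  raw
}

#' Scan a sequence with a PWM
#'
#' Reports every position (on both strands by default) whose relative
#' score reaches `min_relative`. Reverse-strand hits are reported in
#' forward coordinates (0-based start of the motif occurrence on the
#' forward strand) with strand `"-"`.
#'
#' @param sequence A character scalar over A, C, G, T, N.
#' @param pwm_obj A [pwm()].
#' @param min_relative Minimum relative score in `[0, 1]` (0.8 = the usual
#'   80% threshold).
#' @param both_strands Scan the reverse complement too.
#' @return Tibble of hits: `position` (0-based), `strand`, `raw_score`,
#'   `relative_score`, sorted by position then strand.
#' @export
pwm_scan <- function(sequence, pwm_obj, min_relative = 0.8,
                     both_strands = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  smat <- pwm_score_matrix(pwm_obj)
  w <- ncol(smat)
  smin <- sum(apply(smat, 2, min))
  smax <- sum(apply(smat, 2, max))
  empty <- tibble::tibble(position = integer(), strand = character(),
                          raw_score = numeric(), relative_score = numeric())
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < w) return(empty)
  scan_one <- function(seq_chars, strand) {
    idx <- match(seq_chars, c("A", "C", "G", "T"))
    raw <- pwm_raw_scores(idx, smat)
    rel <- (raw - smin) / (smax - smin)
    hit <- which(rel >= min_relative)
    if (!length(hit)) return(empty)
    pos0 <- hit - 1L
    if (strand == "-") pos0 <- L - w - pos0
    tibble::tibble(position = as.integer(pos0), strand = strand,
                   raw_score = raw[hit], relative_score = rel[hit])
  }
  out <- scan_one(chars, "+")
  if (both_strands) {
    rc <- strsplit(revcomp(sequence), "")[[1]]
    out <- dplyr::bind_rows(out, scan_one(rc, "-"))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Best motif at peak summits
#'
#' Scans the window of `window_bp` bases centered at each peak summit
#' (clipped to the chromosome) and keeps the single hit with the highest
#' raw score; ties break to the leftmost position, then to the `+` strand.
#' Peaks without a hit at `min_relative` get missing motif columns. The
#' peak `strand` column is set to the winning motif's orientation.
#'
#' @param peaks Peak tibble with `chrom` and `summit` (see
#'   [read_bed_peaks()]).
#' @param genome Named character vector of chromosome sequences.
#' @param pwm_obj A [pwm()].
#' @param window_bp Summit window width.
#' @param min_relative Relative-score threshold.
#' @return `peaks` with `strand`, `motif_position` (absolute 0-based),
#'   `motif_raw_score`, `motif_relative_score` added.
#' @export
best_motif_at_peak <- function(peaks, genome, pwm_obj, window_bp = 50L,
                               min_relative = 0.8) {
  res <- purrr::map(seq_len(nrow(peaks)), function(k) {
    ch <- peaks$chrom[k]
    if (!ch %in% names(genome)) return(NULL)
    len <- nchar(genome[[ch]])
    lo <- max(0L, peaks$summit[k] - window_bp %/% 2L)
    hi <- min(len, peaks$summit[k] + window_bp %/% 2L)
    if (hi - lo < pwm_obj$width) return(NULL)
    sub <- substr(genome[[ch]], lo + 1L, hi)
    hits <- pwm_scan(sub, pwm_obj, min_relative = min_relative)
    if (nrow(hits) == 0L) return(NULL)
    best <- hits |>
      dplyr::arrange(dplyr::desc(.data$raw_score), .data$position,
                     .data$strand) |>
      dplyr::slice(1)
    best$position <- best$position + lo
    best
  })
  peaks$strand <- purrr::map_chr(res, ~ if (is.null(.x)) NA_character_ else .x$strand)
  peaks$motif_position <- purrr::map_int(res, ~ if (is.null(.x)) NA_integer_ else .x$position)
  peaks$motif_raw_score <- purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$raw_score)
  peaks$motif_relative_score <- purrr::map_dbl(res, ~ if (is.null(.x)) NA_real_ else .x$relative_score)
  peaks
}
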