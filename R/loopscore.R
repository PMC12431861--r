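# Per-loop quantification on balanced matrices: 5x5 signal window, randomly
# sampled donut background, loop score (LS), APA, architectural
# classification, and consistency-based differential loop calls.

# Mean/sum over the (2h+1)^2 window centered at 0-based (ci, cj).
# Masked cells contribute 0 to the sum and are excluded from the mean's
# denominator. Returns NULL when the window leaves the matrix.
window_stats <- function(values, valid, ci, cj, hw) {
  n <- nrow(values)
  ri <- (ci - hw):(ci + hw)
  rj <- (cj - hw):(cj + hw)
  if (ri[1] < 0L || rj[1] < 0L || ri[length(ri)] >= n || rj[length(rj)] >= n) {
    return(NULL)
  }
  w <- values[ri + 1L, rj + 1L, drop = FALSE]
  ok <- outer(valid[ri + 1L], valid[rj + 1L], "&")
  list(mean = if (any(ok)) mean(w[ok]) else NA_real_,
       sum = sum(w[ok]), n_cells = sum(ok))
}

#' Loop signal and loop strength
#'
#' For each loop, the mean (`signal_mean`) and the sum (`strength_sum`) of
#' the normalized signal in the `(2*halfwidth+1)`-pixel square centered at
#' the loop centroid (5 x 5 by default). Loops whose window leaves the
#' matrix are flagged `scoreable = FALSE`, never dropped.
#'
#' @param loops Loop tibble with 0-based centroid bins `bin_i`, `bin_j`
#'   (see [read_bedpe()]).
#' @param bm A `balanced_matrix`.
#' @param halfwidth Window half-width in bins.
#' @return `loops` with `signal_mean`, `strength_sum`, `scoreable` added.
#' @export
loop_signal <- function(loops, bm, halfwidth = 2L) {
  stopifnot(inherits(bm, "contact_matrix"))
  st <- purrr::map(seq_len(nrow(loops)), function(k) {
    window_stats(bm$values, bm$valid, loops$bin_i[k], loops$bin_j[k],
                 halfwidth)
  })
  loops$signal_mean <- purrr::map_dbl(st, ~ if (is.null(.x)) NA_real_ else .x$mean)
  loops$strength_sum <- purrr::map_dbl(st, ~ if (is.null(.x)) NA_real_ else .x$sum)
  loops$scoreable <- !purrr::map_lgl(st, is.null)
  loops
}

#' Candidate donut square offsets
#'
#' All integer offsets `(dx, dy)` at Chebyshev distance exactly
#' `ring_radius` from the loop centroid - the centers of candidate
#' background squares. For the default radius 8 there are exactly 64
#' offsets (`4 * (2 * 8 + 1) - 4`).
#'
#' @param ring_radius Ring radius in bins.
#' @return Tibble with `dx`, `dy`.
#' @export
donut_ring_offsets <- function(ring_radius = 8L) {
  r <- as.integer(ring_radius)
  g <- expand.grid(dx = (-r):r, dy = (-r):r)
  g <- g[pmax(abs(g$dx), abs(g$dy)) == r, ]
  tibble::tibble(dx = as.integer(g$dx), dy = as.integer(g$dy)) |>
    dplyr::arrange(.data$dx, .data$dy)
}

# Usable candidate offsets for a loop at (ci, cj): the square must stay
# inside the matrix, must not cross or touch the diagonal (no cell with
# row >= col), and must not overlap the central exclusion zone
# ((2*exclude_halfwidth+1)^2 around the centroid).
usable_donut_offsets <- function(n, ci, cj, ring_radius, hw,
                                 exclude_halfwidth = 4L) {
  off <- donut_ring_offsets(ring_radius)
  ci2 <- ci + off$dx
  cj2 <- cj + off$dy
  inside <- ci2 - hw >= 0L & cj2 - hw >= 0L &
    ci2 + hw <= n - 1L & cj2 + hw <= n - 1L
  upper <- (ci2 + hw) < (cj2 - hw)
  core <- abs(off$dx) <= exclude_halfwidth + hw &
    abs(off$dy) <= exclude_halfwidth + hw
  off[inside & upper & !core, , drop = FALSE]
}

#' Donut background of loops
#'
#' Estimates the local expected signal of each loop as the mean of the
#' per-square means of `n_samples` 5 x 5 squares drawn uniformly without
#' replacement from the ring of candidate centers at Chebyshev distance
#' `ring_radius` from the centroid (all remaining candidates are used when
#' fewer than `n_samples` survive the bounds/diagonal filters). Each loop
#' uses an RNG stream derived from `(seed, bin_i, bin_j)`, so results do
#' not depend on loop order.
#'
#' @inheritParams loop_signal
#' @param seed Integer global seed.
#' @param n_samples Squares to draw per loop.
#' @param ring_radius Candidate ring radius in bins.
#' @return `loops` with `background`, `n_background` added (`NA`/0 and
#'   `scoreable = FALSE` when no candidate square is usable).
#' @export
donut_background <- function(loops, bm, seed, n_samples = 15L,
                             ring_radius = 8L, halfwidth = 2L) {
  stopifnot(inherits(bm, "contact_matrix"))
  n <- n_bins(bm)
  bg <- rep(NA_real_, nrow(loops))
  nb <- integer(nrow(loops))
  for (k in seq_len(nrow(loops))) {
    ci <- loops$bin_i[k]
    cj <- loops$bin_j[k]
    off <- usable_donut_offsets(n, ci, cj, ring_radius, halfwidth)
    if (nrow(off) == 0L) next
    take <- min(n_samples, nrow(off))
    pick <- local_seed(derive_seed(seed, ci, cj),
                       sample.int(nrow(off), take))
    means <- purrr::map_dbl(pick, function(p) {
      window_stats(bm$values, bm$valid, ci + off$dx[p], cj + off$dy[p],
                   halfwidth)$mean
    })
    means <- means[!is.na(means)]
    if (length(means)) {
      bg[k] <- mean(means)
      nb[k] <- length(means)
    }
  }
  loops$background <- bg
  loops$n_background <- nb
  if (!"scoreable" %in% names(loops)) loops$scoreable <- TRUE
  loops$scoreable <- loops$scoreable & !is.na(bg)
  loops
}

#' Loop score (LS)
#'
#' Quantifies each loop as `ls = log2((signal_mean + eps) /
#' (background + eps))`: the log2 ratio of the mean normalized signal in
#' the 5 x 5 centroid window to the randomly sampled donut background. The
#' pseudocount `eps` guards against zero background.
#'
#' @inheritParams donut_background
#' @param eps Pseudocount added to numerator and denominator.
#' @return `loops` with `signal_mean`, `strength_sum`, `background`,
#'   `n_background`, `ls` and `scoreable` columns.
#' @export
score_loops <- function(loops, bm, seed, n_samples = 15L, ring_radius = 8L,
                        halfwidth = 2L, eps = 1e-9) {
  loops <- loop_signal(loops, bm, halfwidth = halfwidth)
  loops <- donut_background(loops, bm, seed, n_samples = n_samples,
                            ring_radius = ring_radius, halfwidth = halfwidth)
  loops$ls <- log2((loops$signal_mean + eps) / (loops$background + eps))
  loops$ls[!loops$scoreable] <- NA_real_
  loops
}

#' Annotate loop anchors with oriented motif peaks
#'
#' Marks, per loop, whether the upstream (5') anchor overlaps at least one
#' peak carrying a forward-oriented motif and whether the downstream (3')
#' anchor overlaps at least one reverse-oriented one - the convergent
#' configuration expected at architectural loops.
#'
#' @param loops Loop tibble.
#' @param oriented_peaks Peak tibble with a `strand` column (`"+"`/`"-"`,
#'   the motif orientation, for example from [best_motif_at_peak()]).
#' @return `loops` with logical `forward5`, `reverse3` added.
#' @export
annotate_loop_anchors <- function(loops, oriented_peaks) {
  fwd <- oriented_peaks[!is.na(oriented_peaks$strand) &
                          oriented_peaks$strand == "+", , drop = FALSE]
  rev_ <- oriented_peaks[!is.na(oriented_peaks$strand) &
                           oriented_peaks$strand == "-", , drop = FALSE]
  a5 <- tibble::tibble(chrom = loops$chrom, start = loops$start5,
                       end = loops$end5)
  a3 <- tibble::tibble(chrom = loops$chrom, start = loops$start3,
                       end = loops$end3)
  loops$forward5 <- overlaps_any(a5, fwd)
  loops$reverse3 <- overlaps_any(a3, rev_)
  loops
}

#' Architectural loops
#'
#' The high-confidence subset: loops with `ls` strictly greater than
#' `ls_threshold` whose anchors carry convergent motifs (forward motif on
#' the 5' anchor, reverse motif on the 3' anchor). Loops without motif
#' annotation are never architectural.
#'
#' @param scored Loop tibble with `ls` plus `forward5`/`reverse3` (see
#'   [score_loops()], [annotate_loop_anchors()]).
#' @param ls_threshold LS cut-off (strict inequality).
#' @return The architectural subset of `scored`.
#' @export
classify_architectural <- function(scored, ls_threshold = 1) {
  stopifnot(all(c("ls", "forward5", "reverse3") %in% names(scored)))
  dplyr::filter(scored, !is.na(.data$ls), .data$ls > ls_threshold,
                .data$forward5, .data$reverse3)
}

#' Aggregate peak analysis (APA)
#'
#' Averages `(2*halfwidth+1)`-pixel square sub-matrices centered at the
#' centroids of loops spanning more than `min_distance_bp` of genomic
#' distance. Loops whose window leaves the matrix are dropped and counted.
#' The APA score is the center cell divided by the mean of the lower-left
#' 6 x 6 corner block (the short-distance corner).
#'
#' @inheritParams loop_signal
#' @param halfwidth Window half-width in bins (21 x 21 by default).
#' @param min_distance_bp Minimum anchor separation (strict).
#' @return An `apa_result`: `window_halfwidth`, `mean_matrix`,
#'   `n_loops_used`, `n_dropped`, `apa_score`.
#' @export
apa <- function(loops, bm, halfwidth = 10L, min_distance_bp = 100000) {
  stopifnot(inherits(bm, "contact_matrix"))
  sep_bp <- (loops$bin_j - loops$bin_i) * bm$resolution
  loops <- loops[sep_bp > min_distance_bp, , drop = FALSE]
  w <- 2L * halfwidth + 1L
  acc <- matrix(0, w, w)
  used <- 0L
  dropped <- 0L
  n <- n_bins(bm)
  for (k in seq_len(nrow(loops))) {
    ri <- (loops$bin_i[k] - halfwidth):(loops$bin_i[k] + halfwidth)
    rj <- (loops$bin_j[k] - halfwidth):(loops$bin_j[k] + halfwidth)
    if (ri[1] < 0L || rj[1] < 0L || ri[w] >= n || rj[w] >= n) {
      dropped <- dropped + 1L
      next
    }
    acc <- acc + bm$values[ri + 1L, rj + 1L]
    used <- used + 1L
  }
  if (used == 0L) stop("no eligible loops for APA")
  mm <- acc / used
  corner <- mm[(w - 5L):w, 1:6]
  structure(
    list(window_halfwidth = as.integer(halfwidth), mean_matrix = mm,
         n_loops_used = used, n_dropped = dropped,
         apa_score = mm[halfwidth + 1L, halfwidth + 1L] / mean(corner)),
    class = "apa_result"
  )
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %d loops, %dx%d window, APA score %.3f\n",
              x$n_loops_used, 2 * x$window_halfwidth + 1,
              2 * x$window_halfwidth + 1, x$apa_score))
  invisible(x)
}

#' @export
tidy.apa_result <- function(x, ...) {
  w <- 2L * x$window_halfwidth + 1L
  tibble::tibble(
    dx = rep(-x$window_halfwidth:x$window_halfwidth, times = w),
    dy = rep(-x$window_halfwidth:x$window_halfwidth, each = w),
    value = as.vector(x$mean_matrix)
  )
}

#' @export
glance.apa_result <- function(x, ...) {
  tibble::tibble(apa_score = x$apa_score, n_loops_used = x$n_loops_used,
                 n_dropped = x$n_dropped,
                 window = 2L * x$window_halfwidth + 1L)
}

#' Condition-specific (differential) loops by replicate consistency
#'
#' Calls a loop weakened in the alternate condition when, in every
#' reference-versus-alternate sample pair, both the loop strength
#' (`strength_sum`) and the loop score (`ls`) are strictly higher in the
#' reference sample; strengthened is the mirror call. Ties or any
#' inconsistent pair leave the loop unchanged. Equivalently: the minimum
#' across reference samples must exceed the maximum across alternate
#' samples (or vice versa) for both statistics.
#'
#' @param quants Long tibble of per-sample loop quantifications: columns
#'   `sample`, `bin_i`, `bin_j`, `strength_sum`, `ls` (for example
#'   [score_loops()] results bound by sample; score every sample with the
#'   same loop list and seed so donut squares match).
#' @param ref_samples,alt_samples Character vectors of sample ids.
#' @return One row per loop with `bin_i`, `bin_j` and
#'   `call` in `c("weakened", "strengthened", "unchanged")`.
#' @export
condition_specific_loops <- function(quants, ref_samples, alt_samples) {
  if (length(ref_samples) == 0L || length(alt_samples) == 0L) {
    stop("both sample groups must be non-empty")
  }
  miss <- setdiff(c(ref_samples, alt_samples), unique(quants$sample))
  if (length(miss)) stop("samples absent from quants: ",
                         paste(miss, collapse = ", "))
  q <- dplyr::filter(quants, .data$sample %in% c(ref_samples, alt_samples))
  q$group <- ifelse(q$sample %in% ref_samples, "ref", "alt")
  q |>
    dplyr::group_by(.data$bin_i, .data$bin_j) |>
    dplyr::summarise(
      ok = all(!is.na(.data$strength_sum)) && all(!is.na(.data$ls)),
      s_ref_min = min(.data$strength_sum[.data$group == "ref"]),
      s_ref_max = max(.data$strength_sum[.data$group == "ref"]),
      s_alt_min = min(.data$strength_sum[.data$group == "alt"]),
      s_alt_max = max(.data$strength_sum[.data$group == "alt"]),
      l_ref_min = min(.data$ls[.data$group == "ref"]),
      l_ref_max = max(.data$ls[.data$group == "ref"]),
      l_alt_min = min(.data$ls[.data$group == "alt"]),
      l_alt_max = max(.data$ls[.data$group == "alt"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      call = dplyr::case_when(
        !.data$ok ~ "unchanged",
        .data$s_ref_min > .data$s_alt_max &
          .data$l_ref_min > .data$l_alt_max ~ "weakened",
        .data$s_alt_min > .data$s_ref_max &
          .data$l_alt_min > .data$l_ref_max ~ "strengthened",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::select("bin_i", "bin_j", "call")
}
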