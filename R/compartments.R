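# A/B compartment eigenvector selection and saddle construction.

#' Compartment eigenvector
#'
#' Expected-normalizes the balanced matrix, computes the Pearson
#' correlation matrix over valid bins, extracts its first `n_eigen`
#' eigenvectors, selects the one with the highest absolute Pearson
#' correlation with the phasing track (for example GC% or gene density),
#' and orients it so that the correlation is positive - positive values
#' then mark the A compartment.
#'
#' @param bm A `balanced_matrix`.
#' @param phasing Per-bin phasing values: a numeric vector of length
#'   `n_bins(bm)` or a track tibble with one row per bin and a `value`
#'   column.
#' @param n_eigen Number of candidate eigenvectors.
#' @return A `compartment_result`: `eigenvectors` (n x n_eigen, `NA` on
#'   invalid bins), `chosen_index`, `chosen` (oriented per-bin vector),
#'   `correlation_with_phasing`, `valid`, `chrom`, `resolution`; `saddle`
#'   and `quantile_edges` are filled by [saddle()].
#' @export
compartment_eigenvector <- function(bm, phasing, n_eigen = 3L) {
  stopifnot(inherits(bm, "balanced_matrix"))
  n <- n_bins(bm)
  ph <- if (is.data.frame(phasing)) phasing$value else phasing
  stopifnot(length(ph) == n)
  oe <- oe_matrix(bm)
  valid <- bm$valid
  sub <- oe[valid, valid, drop = FALSE]
  keep <- apply(sub, 2, stats::var) > 0
  valid[valid][!keep] <- FALSE
  sub <- oe[valid, valid, drop = FALSE]
  if (sum(valid) < 10L) stop("fewer than 10 valid bins")
  cc <- stats::cor(sub)
  eg <- eigen(cc, symmetric = TRUE)
  k <- min(n_eigen, ncol(eg$vectors))
  evs <- matrix(NA_real_, n, k)
  evs[valid, ] <- eg$vectors[, seq_len(k), drop = FALSE]
  rs <- vapply(seq_len(k), function(j) {
    suppressWarnings(cor(evs[valid, j], ph[valid]))
  }, numeric(1))
  rs[is.na(rs)] <- 0
  chosen_index <- which.max(abs(rs))
  chosen <- evs[, chosen_index]
  r <- rs[chosen_index]
  if (r < 0) {
    chosen <- -chosen
    r <- -r
  }
  structure(
    list(eigenvectors = evs, chosen_index = chosen_index, chosen = chosen,
         correlation_with_phasing = r, valid = valid, chrom = bm$chrom,
         resolution = bm$resolution, saddle = NULL, quantile_edges = NULL),
    class = "compartment_result"
  )
}

#' @export
print.compartment_result <- function(x, ...) {
  cat(sprintf(
    "<compartment_result> %s: eigenvector %d, |r| with phasing = %.3f%s\n",
    x$chrom, x$chosen_index, x$correlation_with_phasing,
    if (is.null(x$saddle)) "" else sprintf(", %dx%d saddle",
                                           nrow(x$saddle), ncol(x$saddle))
  ))
  invisible(x)
}

#' @export
tidy.compartment_result <- function(x, ...) {
  n <- length(x$chosen)
  tibble::tibble(
    chrom = x$chrom, bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * x$resolution,
    end = seq_len(n) * x$resolution,
    eigenvector = x$chosen,
    compartment = dplyr::case_when(
      is.na(x$chosen) ~ NA_character_,
      x$chosen >= 0 ~ "A", TRUE ~ "B"
    )
  )
}

#' @export
glance.compartment_result <- function(x, ...) {
  tibble::tibble(
    chosen_index = x$chosen_index,
    correlation_with_phasing = x$correlation_with_phasing,
    n_valid = sum(x$valid),
    has_saddle = !is.null(x$saddle)
  )
}

#' Compartment saddle
#'
#' Assigns valid bins to `n_q` equal-occupancy quantiles of the chosen
#' eigenvector (lowest = strongest B, highest = strongest A) and averages
#' the observed/expected signal over every quantile pair, excluding the
#' diagonal. Row/column order runs lowest to highest, so the upper-left
#' corner summarizes B-B and the lower-right corner A-A preference.
#'
#' @param bm The `balanced_matrix` the eigenvector came from.
#' @param result A [compartment_eigenvector()] result.
#' @param n_q Number of quantile bins.
#' @return `result` with `saddle` (n_q x n_q matrix) and `quantile_edges`
#'   filled in.
#' @export
saddle <- function(bm, result, n_q = 50L) {
  stopifnot(inherits(result, "compartment_result"))
  ev <- result$chosen
  valid <- result$valid & !is.na(ev)
  m <- sum(valid)
  if (n_q > m) stop("n_q exceeds the number of valid bins")
  oe <- oe_matrix(bm)
  sub <- oe[valid, valid, drop = FALSE]
  q <- dplyr::ntile(ev[valid], n_q)
  ind <- matrix(0, m, n_q)
  ind[cbind(seq_len(m), q)] <- 1
  nodiag <- sub
  diag(nodiag) <- 0
  ones <- matrix(1, m, m)
  diag(ones) <- 0
  sums <- t(ind) %*% nodiag %*% ind
  cnts <- t(ind) %*% ones %*% ind
  result$saddle <- sums / cnts
  result$quantile_edges <- stats::quantile(ev[valid],
                                           probs = seq(0, 1, length.out = n_q + 1L))
  result
}
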