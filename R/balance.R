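#' Iterative proportional fit (IPF) matrix balancing
#'
#' Removes multiplicative per-bin biases from a raw contact matrix by a
#' symmetric Sinkhorn-style iteration: a single weight vector is applied to
#' rows and columns (`normalized = raw * w_i * w_j`), and at each step the
#' weights of valid bins are scaled by `sqrt(target / marginal)`. The target
#' marginal is the mean valid marginal of the raw matrix (scale-preserving,
#' so normalized values stay comparable across similarly sequenced
#' samples). Convergence is declared when the coefficient of variation of
#' the valid-bin marginals falls below `tol`.
#'
#' Bins with a zero raw marginal are masked invalid and excluded.
#'
#' @param x A [contact_matrix()].
#' @param tol Tolerance on the marginal coefficient of variation.
#' @param max_iter Maximum number of iterations; if reached, the result is
#'   flagged unconverged with a warning.
#' @return A `balanced_matrix` (inherits `contact_matrix`): fields `chrom`,
#'   `resolution`, `values` (normalized), `valid`, `weights`,
#'   `n_iterations`, `converged`, `marginal_cv`.
#' @export
ipf_balance <- function(x, tol = 1e-5, max_iter = 200L) {
  stopifnot(inherits(x, "contact_matrix"))
  raw <- x$values
  marg0 <- rowSums(raw)
  valid <- x$valid & marg0 > 0
  if (sum(valid) < 2L) stop("need at least 2 valid (non-zero) bins")
  n <- nrow(raw)
  target <- sum(raw[valid, valid]) / sum(valid)
  if (target <= 0) stop("all-zero matrix")

  w <- rep(0, n)
  w[valid] <- 1
  sub <- raw[valid, valid, drop = FALSE]
  wv <- w[valid]
  it <- 0L
  cv <- Inf
  while (it < max_iter) {
    it <- it + 1L
    m <- as.vector(sub %*% wv) * wv
    cv <- sd(m) / mean(m)
    if (is.finite(cv) && cv < tol) break
    wv <- wv * sqrt(target / m)
  }
  m <- as.vector(sub %*% wv) * wv
  cv <- sd(m) / mean(m)
  converged <- is.finite(cv) && cv < tol
  if (!converged) warning("IPF did not converge in ", max_iter, " iterations")

  w[valid] <- wv
  norm <- raw * outer(w, w)
  structure(
    list(chrom = x$chrom, resolution = x$resolution, values = norm,
         valid = valid, weights = w, n_iterations = it,
         converged = converged, marginal_cv = cv),
    class = c("balanced_matrix", "contact_matrix")
  )
}

#' @export
glance.balanced_matrix <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, n_bins = n_bins(x), n_valid = sum(x$valid),
    n_iterations = x$n_iterations, converged = x$converged,
    marginal_cv = x$marginal_cv
  )
}

#' Write per-bin balancing weights as two-column text
#' @param x A `balanced_matrix`.
#' @param path Output file (0-based bin id, weight).
#' @return `path`, invisibly.
#' @export
write_weights <- function(x, path) {
  readr::write_tsv(
    tibble::tibble(bin = seq_len(n_bins(x)) - 1L, weight = x$weights),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Median contact signal as a function of genomic distance
#'
#' For each off-diagonal `d >= 1`, the median of normalized values over
#' valid bin pairs at bin separation `d`. With several chromosomes, a
#' cross-chromosome median-of-medians is appended as chromosome `"all"`;
#' chromosomes can be excluded from that summary (mirroring analyses that
#' drop a chromosome with library-specific artefacts).
#'
#' @param x A `balanced_matrix` or a (possibly named) list of them.
#' @param exclude_chroms Chromosome names left out of the summary.
#' @return A tibble `chrom`, `distance_bins`, `distance_bp`,
#'   `median_value`.
#' @export
distance_decay <- function(x, exclude_chroms = NULL) {
  if (inherits(x, "contact_matrix")) x <- list(x)
  curves <- purrr::map_dfr(x, function(bm) {
    stopifnot(inherits(bm, "balanced_matrix"))
    n <- n_bins(bm)
    v <- bm$values
    ok <- bm$valid
    med <- vapply(seq_len(n - 1L), function(d) {
      i <- seq_len(n - d)
      keep <- ok[i] & ok[i + d]
      if (!any(keep)) return(NA_real_)
      median(v[cbind(i[keep], i[keep] + d)])
    }, numeric(1))
    tibble::tibble(chrom = bm$chrom, distance_bins = seq_len(n - 1L),
                   distance_bp = seq_len(n - 1L) * bm$resolution,
                   median_value = med)
  })
  keep <- dplyr::filter(curves, !.data$chrom %in% exclude_chroms)
  if (length(unique(keep$chrom)) > 1L) {
    summ <- keep |>
      dplyr::group_by(.data$distance_bins, .data$distance_bp) |>
      dplyr::summarise(
        median_value = median(.data$median_value, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(chrom = "all", .before = 1)
    curves <- dplyr::bind_rows(curves, summ)
  }
  curves
}

# Per-distance expected values (mean over valid pairs at each separation,
# including d = 0) and the observed/expected matrix.
expected_by_distance <- function(bm) {
  n <- n_bins(bm)
  v <- bm$values
  ok <- bm$valid
  vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    keep <- ok[i] & ok[i + d]
    if (!any(keep)) return(NA_real_)
    mean(v[cbind(i[keep], i[keep] + d)])
  }, numeric(1))
}

#' Observed/expected transform of a balanced matrix
#'
#' Divides each cell by the mean normalized value at its bin separation
#' (computed over valid pairs). Cells involving invalid bins are set to
#' `NA`.
#'
#' @param bm A `balanced_matrix`.
#' @return A dense numeric matrix of observed/expected ratios.
#' @export
oe_matrix <- function(bm) {
  stopifnot(inherits(bm, "balanced_matrix"))
  n <- n_bins(bm)
  exp_d <- expected_by_distance(bm)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  oe <- bm$values / matrix(exp_d[d + 1L], n, n)
  oe[!bm$valid, ] <- NA_real_
  oe[, !bm$valid] <- NA_real_
  oe
}
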