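#' Binned intra-chromosomal contact matrix
#'
#' Container for one chromosome's binned, symmetric, non-negative Hi-C
#' contact map. Bins whose raw marginal is zero are treated as unmappable
#' ("invalid"): their rows and columns are forced to zero and they are
#' excluded from balancing, insulation, compartment and loop statistics.
#'
#' @param values Dense symmetric numeric matrix of non-negative contact
#'   counts or normalized values.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp (default 10 kb, the working resolution of
#'   ligation-frequency matrices here).
#' @param valid Optional logical vector marking mappable bins. Defaults to
#'   bins with a positive marginal.
#' @return An object of class `contact_matrix` with fields `chrom`,
#'   `resolution`, `values`, `valid`.
#' @export
contact_matrix <- function(values, chrom = "chrS", resolution = 10000L,
                           valid = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (any(values < 0)) stop("contact matrix values must be non-negative")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("contact matrix must be symmetric")
  }
  n <- nrow(values)
  if (is.null(valid)) valid <- rowSums(values) > 0
  stopifnot(length(valid) == n)
  values[!valid, ] <- 0
  values[, !valid] <- 0
  structure(
    list(chrom = chrom, resolution = as.integer(resolution),
         values = values, valid = valid),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<%s> %s: %d bins @ %d bp (%d valid)\n",
              class(x)[1], x$chrom, n_bins(x), x$resolution, sum(x$valid)))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param x A `contact_matrix`.
#' @return Integer bin count.
#' @export
n_bins <- function(x) nrow(x$values)

#' Tidy a contact matrix into sparse triplets
#'
#' @param x A `contact_matrix` (or `balanced_matrix`).
#' @param ... Unused.
#' @return A tibble with 0-based `bin_i`, `bin_j` (upper triangle, including
#'   the diagonal) and `value`, non-zero entries only.
#' @export
tidy.contact_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values, diag = TRUE) & x$values != 0,
               arr.ind = TRUE)
  tibble::tibble(
    bin_i = as.integer(idx[, 1] - 1L),
    bin_j = as.integer(idx[, 2] - 1L),
    value = x$values[idx]
  ) |> dplyr::arrange(.data$bin_i, .data$bin_j)
}

#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, resolution = x$resolution, n_bins = n_bins(x),
    n_valid = sum(x$valid), total = sum(x$values[upper.tri(x$values, TRUE)])
  )
}
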