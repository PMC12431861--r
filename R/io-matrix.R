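# Triplet-text contact matrix interchange: "bin_i<TAB>bin_j<TAB>value" with
# an optional sidecar bin table (chrom, start, end, bin id). The "triplet"
# dialect uses 0-based bin ids; the "hicpro" dialect uses the 1-based ids of
# HiC-Pro matrix/bed pairs.

#' Read a contact matrix from sparse triplet text
#'
#' Reads `bin_i<TAB>bin_j<TAB>value` records into a dense symmetric
#' [contact_matrix()]. Entries may be given in either triangle; they are
#' mirrored, and duplicate `(i, j)` records (in any orientation) are summed.
#' Bins absent from the file are zero.
#'
#' @param path Triplet text file.
#' @param dialect `"triplet"` (0-based ids) or `"hicpro"` (1-based ids with a
#'   `bins` sidecar table).
#' @param n_bins Number of bins; required unless `bins` is given.
#' @param bins Optional sidecar bin table path (TSV: chrom, start, end, id)
#'   from which `n_bins`, `chrom` and `resolution` are inferred.
#' @param chrom,resolution Metadata used when no `bins` table is given.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, dialect = c("triplet", "hicpro"),
                                n_bins = NULL, bins = NULL,
                                chrom = "chrS", resolution = 10000L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(bins)) {
    bt <- readr::read_tsv(bins, col_names = c("chrom", "start", "end", "id"),
                          col_types = "ciii", progress = FALSE)
    n_bins <- nrow(bt)
    chrom <- bt$chrom[1]
    resolution <- as.integer(bt$end[1] - bt$start[1])
  }
  if (is.null(n_bins)) stop("n_bins or a bins table is required")
  n_bins <- as.integer(n_bins)

  df <- readr::read_tsv(path, col_names = c("bin_i", "bin_j", "value"),
                        col_types = "iid", progress = FALSE)
  if (dialect == "hicpro") {
    df$bin_i <- df$bin_i - 1L
    df$bin_j <- df$bin_j - 1L
  }
  bad <- which(df$value < 0)
  if (length(bad)) stop("negative count at line ", bad[1])
  oob <- which(df$bin_i < 0L | df$bin_j < 0L |
                 df$bin_i >= n_bins | df$bin_j >= n_bins)
  if (length(oob)) stop("bin index out of range at line ", oob[1])

  m <- matrix(0, n_bins, n_bins)
  ii <- pmin(df$bin_i, df$bin_j) + 1L
  jj <- pmax(df$bin_i, df$bin_j) + 1L
  for (k in seq_along(ii)) m[ii[k], jj[k]] <- m[ii[k], jj[k]] + df$value[k]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as sparse triplet text
#'
#' Emits the non-zero upper triangle (diagonal included) in deterministic
#' row-major order, 0-based ids, plus an optional sidecar bin table.
#'
#' @param x A `contact_matrix` or `balanced_matrix`.
#' @param path Output triplet file.
#' @param bins Optional path for the sidecar bin table.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(x, path, bins = NULL) {
  tr <- tidy(x)
  readr::write_tsv(tr, path, col_names = FALSE, progress = FALSE)
  if (!is.null(bins)) {
    n <- n_bins(x)
    bt <- tibble::tibble(
      chrom = x$chrom,
      start = (seq_len(n) - 1L) * x$resolution,
      end = seq_len(n) * x$resolution,
      id = seq_len(n) - 1L
    )
    readr::write_tsv(bt, bins, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
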