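# BED / narrowPeak / BEDPE / bedGraph / FASTA / JASPAR-PFM readers and
# writers. All tables come back as tibbles in 0-based half-open coordinates;
# writers emit deterministic column and line order.

#' Read a BEDPE loop list
#'
#' Loads loop anchor pairs and assigns centroid bins at the stated matrix
#' resolution (the bin containing each anchor's midpoint). Anchors are
#' reordered so the upstream (5') anchor precedes the downstream (3') one.
#' Inter-chromosomal records, and records whose two anchors fall into the
#' same bin, are skipped; their counts are attached as attributes
#' `n_interchromosomal` and `n_same_bin`.
#'
#' @param path BEDPE file (>= 6 tab-separated columns).
#' @param resolution Matrix bin size in bp used for centroid assignment.
#' @return A loop tibble with columns `chrom`, `start5`, `end5`, `start3`,
#'   `end3` and 0-based centroid bins `bin_i < bin_j`.
#' @export
read_bedpe <- function(path, resolution = 10000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty BEDPE: ", path)
    return(loop_tibble())
  }
  if (ncol(raw) < 6L) stop("BEDPE needs >= 6 columns: ", path)
  df <- tibble::tibble(
    chrom1 = as.character(raw[[1]]), start1 = as.integer(raw[[2]]),
    end1 = as.integer(raw[[3]]),
    chrom2 = as.character(raw[[4]]), start2 = as.integer(raw[[5]]),
    end2 = as.integer(raw[[6]])
  )
  bad <- which(is.na(df$start1) | is.na(df$end1) | is.na(df$start2) |
                 is.na(df$end2) | df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad)) stop("malformed coordinates at line ", bad[1])

  inter <- df$chrom1 != df$chrom2
  df <- df[!inter, , drop = FALSE]

  mid1 <- interval_midpoint(df$start1, df$end1)
  mid2 <- interval_midpoint(df$start2, df$end2)
  swap <- mid1 > mid2
  loops <- tibble::tibble(
    chrom  = df$chrom1,
    start5 = ifelse(swap, df$start2, df$start1),
    end5   = ifelse(swap, df$end2, df$end1),
    start3 = ifelse(swap, df$start1, df$start2),
    end3   = ifelse(swap, df$end1, df$end2)
  )
  loops$bin_i <- bin_of(interval_midpoint(loops$start5, loops$end5), resolution)
  loops$bin_j <- bin_of(interval_midpoint(loops$start3, loops$end3), resolution)
  same_bin <- loops$bin_i == loops$bin_j
  loops <- loops[!same_bin, , drop = FALSE]
  attr(loops, "n_interchromosomal") <- sum(inter)
  attr(loops, "n_same_bin") <- sum(same_bin)
  loops
}

loop_tibble <- function() {
  tibble::tibble(chrom = character(), start5 = integer(), end5 = integer(),
                 start3 = integer(), end3 = integer(),
                 bin_i = integer(), bin_j = integer())
}

#' Write a loop tibble as BEDPE
#' @param loops A loop tibble (see [read_bedpe()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  out <- tibble::tibble(
    chrom1 = loops$chrom, start1 = loops$start5, end1 = loops$end5,
    chrom2 = loops$chrom, start2 = loops$start3, end2 = loops$end3
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read peaks from BED or narrowPeak
#'
#' For 10-column narrowPeak input the 10th column is the summit offset from
#' `start` (`-1` meaning unknown); otherwise, and for plain BED, the summit
#' defaults to the interval midpoint.
#'
#' @param path BED3+/BED6/narrowPeak file.
#' @return A peak tibble with `chrom`, `start`, `end`, `name`, `summit`
#'   (absolute bp) and, when present, `strand`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty peak file: ", path)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          summit = integer()))
  }
  if (ncol(raw) < 3L) stop("BED needs >= 3 columns: ", path)
  pk <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4L) as.character(raw[[4]])
           else sprintf("peak_%d", seq_len(nrow(raw)))
  )
  bad <- which(is.na(pk$start) | is.na(pk$end) | pk$start < 0 |
                 pk$start >= pk$end)
  if (length(bad)) stop("malformed coordinates at line ", bad[1])
  if (ncol(raw) >= 6L) pk$strand <- as.character(raw[[6]])
  summit <- interval_midpoint(pk$start, pk$end)
  if (ncol(raw) >= 10L) {
    off <- suppressWarnings(as.integer(raw[[10]]))
    has <- !is.na(off) & off >= 0L
    summit[has] <- pk$start[has] + off[has]
  }
  pk$summit <- summit
  pk
}

#' Write peaks as BED6 (strand column carries motif orientation)
#' @param peaks Peak tibble; a `strand` column is used if present.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  out <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name
           else sprintf("peak_%d", seq_len(nrow(peaks))),
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write a bedGraph coverage track
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @return A track tibble `chrom`, `start`, `end`, `value`. Bases not
#'   covered by any record are missing, never implicitly zero.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", progress = FALSE)
  if (nrow(df) == 0L) warning("empty bedGraph: ", path)
  df
}

#' @rdname read_bedgraph
#' @param track Track tibble to write.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Sequences are returned as a named character vector, uppercased, with any
#' non-ACGT letter preserved as `N`.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    warning("empty FASTA: ", path)
    return(character(0))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Position weight matrix
#'
#' Builds a PWM from a count (or probability) matrix with rows A, C, G, T.
#' Counts are regularized with a pseudocount and converted to per-column
#' probabilities.
#'
#' @param counts 4 x width numeric matrix, rows in A, C, G, T order.
#' @param pseudocount Added to every cell before normalization.
#' @param background Background base probabilities (A, C, G, T), summing
#'   to 1.
#' @param name Motif name.
#' @return An object of class `pwm` with fields `name`, `width`, `prob`,
#'   `background`.
#' @export
pwm <- function(counts, pseudocount = 0.01,
                background = rep(0.25, 4), name = "motif") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L, all(counts >= 0))
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
                "/")
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(name = name, width = ncol(prob), prob = prob,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n",
              x$name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param x A `pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
}

#' Read / write a JASPAR-style PFM
#'
#' Accepts the JASPAR text layout (`>ID name` header then four rows
#' `A [ 1 2 3 ]` ...) or four bare rows of counts in A, C, G, T order.
#'
#' @param path PFM file.
#' @param pseudocount Passed to [pwm()].
#' @return A [pwm()].
#' @export
read_pfm <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop("PFM needs 4 count rows: ", path)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1L) stop("PFM rows have unequal width: ", path)
  pwm(do.call(rbind, rows), pseudocount = pseudocount, name = name)
}

#' @rdname read_pfm
#' @param x A `pwm` (probabilities are written, 4 decimal places are not
#'   rounded: full precision).
#' @export
write_pfm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(x$prob[b, ], digits = 15),
                             collapse = " ")), con)
  }
  invisible(path)
}
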