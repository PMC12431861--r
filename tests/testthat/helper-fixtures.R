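# Shared fixtures: constructed balanced matrices, a toy PWM, and the
# independent brute-force PWM scanner used as the oracle.

# Wrap a plain symmetric matrix as an already-balanced matrix (unit
# weights), for unit tests that exercise downstream statistics on
# constructed values.
as_balanced <- function(values, chrom = "chrS", resolution = 10000L,
                        valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  structure(
    list(chrom = chrom, resolution = as.integer(resolution), values = values,
         valid = valid, weights = rep(1, nrow(values)),
         n_iterations = 0L, converged = TRUE, marginal_cv = 0),
    class = c("balanced_matrix", "contact_matrix")
  )
}

# Constant matrix of level c.
const_bm <- function(n, c = 1, resolution = 10000L) {
  as_balanced(matrix(c, n, n), resolution = resolution)
}

# Toy width-4 PWM with unequal, non-palindromic columns.
toy_pwm <- function() {
  counts <- matrix(c(
    8, 1, 0, 2,
    1, 6, 1, 0,
    0, 1, 7, 1,
    1, 0, 0, 5
  ), nrow = 4, byrow = TRUE)  # rows A, C, G, T
  pwm(counts, pseudocount = 0.01, name = "toy")
}

# Independent brute-force PWM scanner: loops over every window and strand,
# scoring base by base. Kept deliberately naive.
brute_scan <- function(sequence, pwm_obj, min_relative = 0.8,
                       both_strands = TRUE) {
  bases <- c("A", "C", "G", "T")
  smat <- log(pwm_obj$prob / pwm_obj$background)
  w <- ncol(smat)
  smin <- sum(apply(smat, 2, min))
  smax <- sum(apply(smat, 2, max))
  score_window <- function(chars) {
    s <- 0
    for (k in seq_len(w)) {
      b <- match(chars[k], bases)
      if (!is.na(b)) s <- s + unname(smat[b, k])
    }
    unname(s)
  }
  hits <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    seq_use <- if (strand == "-") revcomp(sequence) else sequence
    chars <- strsplit(toupper(seq_use), "")[[1]]
    L <- length(chars)
    if (L < w) next
    for (p in 1:(L - w + 1L)) {
      raw <- score_window(chars[p:(p + w - 1L)])
      rel <- (raw - smin) / (smax - smin)
      if (rel >= min_relative) {
        pos0 <- if (strand == "-") L - w - (p - 1L) else p - 1L
        hits[[length(hits) + 1L]] <- tibble::tibble(
          position = as.integer(pos0), strand = strand,
          raw_score = raw, relative_score = rel
        )
      }
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(position = integer(), strand = character(),
                          raw_score = numeric(), relative_score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), position, strand)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
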