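# Synthetic Hi-C / peak / genome generator with retained ground truth.
# Every generator takes an explicit seed and restores the caller's RNG state.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a global seed with integer keys (for example a loop's centroid
#' bins) into a new seed below 2^31, so that per-item random draws do not
#' depend on item order.
#'
#' @param seed Integer global seed.
#' @param ... Further integer keys.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 17
  for (k in ks) h <- (h * 48271 + abs(as.double(k)) + 1) %% 2147483647
  as.integer(h)
}

#' Parameters of the synthetic contact-map generator
#'
#' Defines the expected contact map
#' `e_ij = A (|i-j|+1)^-alpha * prod(boundary gammas) * prod(loop bumps) *
#' (compartment affinity) * b_i b_j`, rescaled so the expected upper-triangle
#' total equals `depth`; observed counts are Poisson draws.
#'
#' @param n_bins Number of bins.
#' @param resolution Bin size in bp.
#' @param alpha Power-law distance-decay exponent (> 0).
#' @param base_level Pre-scaling base level `A` (> 0).
#' @param loops Tibble with `bin_i`, `bin_j` (0-based, `bin_i < bin_j`),
#'   `amplitude` (>= 1) and `spread` (Gaussian bump sd in bins).
#' @param boundaries Tibble with `bin` and `attenuation` in (0, 1]; contacts
#'   whose bins lie strictly on opposite sides of `bin` are multiplied by
#'   `attenuation`.
#' @param compartments Optional per-bin label vector in {"A","B"}.
#' @param compartment_affinity Cross-compartment contact multiplier `rho`
#'   in (0, 1].
#' @param biases Per-bin positive multiplicative biases `b_i`.
#' @param depth Expected total count over the upper triangle (> 0).
#' @param seed Integer seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_bins = 200L, resolution = 10000L, alpha = 1,
                       base_level = 1, loops = NULL, boundaries = NULL,
                       compartments = NULL, compartment_affinity = 1,
                       biases = NULL, depth = 1e6, seed = 1L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L, alpha > 0, base_level > 0,
            compartment_affinity > 0, compartment_affinity <= 1)
  if (depth <= 0) stop("depth must be positive")
  if (is.null(loops)) {
    loops <- tibble::tibble(bin_i = integer(), bin_j = integer(),
                            amplitude = numeric(), spread = numeric())
  }
  loops <- tibble::as_tibble(loops)
  if (nrow(loops)) {
    if (any(loops$bin_i >= loops$bin_j)) {
      stop("loop centroid on or below the diagonal")
    }
    if (any(loops$bin_i < 0L | loops$bin_j >= n_bins)) {
      stop("loop bins out of range")
    }
    if (any(loops$amplitude < 1)) stop("loop amplitude must be >= 1")
  }
  if (is.null(boundaries)) {
    boundaries <- tibble::tibble(bin = integer(), attenuation = numeric())
  }
  boundaries <- tibble::as_tibble(boundaries)
  if (nrow(boundaries) &&
      any(boundaries$attenuation <= 0 | boundaries$attenuation > 1)) {
    stop("boundary attenuation must be in (0, 1]")
  }
  if (!is.null(compartments)) {
    stopifnot(length(compartments) == n_bins,
              all(compartments %in% c("A", "B")))
  }
  if (is.null(biases)) biases <- rep(1, n_bins)
  stopifnot(length(biases) == n_bins, all(biases > 0))
  structure(
    list(n_bins = n_bins, resolution = as.integer(resolution), alpha = alpha,
         base_level = base_level, loops = loops, boundaries = boundaries,
         compartments = compartments,
         compartment_affinity = compartment_affinity,
         biases = biases, depth = depth, seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Expected (noise-free) matrix for a sim_params, scaled to depth.
expected_contact_map <- function(params) {
  n <- params$n_bins
  idx <- seq_len(n) - 1L
  d <- abs(outer(idx, idx, "-"))
  e <- params$base_level * (d + 1)^(-params$alpha)
  for (k in seq_len(nrow(params$boundaries))) {
    b <- params$boundaries$bin[k]
    g <- params$boundaries$attenuation[k]
    left <- idx < b
    right <- idx > b
    cross <- outer(left, right) | outer(right, left)
    e[cross] <- e[cross] * g
  }
  if (nrow(params$loops)) {
    gi <- matrix(idx, n, n)
    gj <- matrix(idx, n, n, byrow = TRUE)
    for (k in seq_len(nrow(params$loops))) {
      bi <- params$loops$bin_i[k]
      bj <- params$loops$bin_j[k]
      lam <- params$loops$amplitude[k]
      s2 <- 2 * params$loops$spread[k]^2
      bump <- 1 + (lam - 1) * (exp(-((gi - bi)^2 + (gj - bj)^2) / s2) +
                                 exp(-((gi - bj)^2 + (gj - bi)^2) / s2))
      e <- e * bump
    }
  }
  if (!is.null(params$compartments)) {
    same <- outer(params$compartments, params$compartments, "==")
    e[!same] <- e[!same] * params$compartment_affinity
  }
  e <- e * outer(params$biases, params$biases)
  e * (params$depth / sum(e[upper.tri(e, diag = TRUE)]))
}

#' Simulate a raw contact map with known ground truth
#'
#' Draws Poisson counts around the expected map defined by [sim_params()]
#' (upper triangle drawn, then mirrored) and returns the raw
#' [contact_matrix()] together with a `synthetic_truth` record: the
#' parameters, the expected matrix, the planted loop list (anchors are the
#' centroid bins' intervals) and the planted boundary list.
#'
#' @param params A [sim_params()].
#' @return A list with elements `matrix` ([contact_matrix()] of counts) and
#'   `truth`.
#' @export
simulate_contact_map <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  e <- expected_contact_map(params)
  n <- params$n_bins
  counts <- matrix(0, n, n)
  up <- which(upper.tri(e, diag = TRUE))
  counts[up] <- local_seed(params$seed, rpois(length(up), e[up]))
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  res <- params$resolution
  truth_loops <- tibble::tibble(
    chrom = "chrS",
    start5 = params$loops$bin_i * res, end5 = (params$loops$bin_i + 1L) * res,
    start3 = params$loops$bin_j * res, end3 = (params$loops$bin_j + 1L) * res,
    bin_i = params$loops$bin_i, bin_j = params$loops$bin_j,
    amplitude = params$loops$amplitude, spread = params$loops$spread
  )
  truth_boundaries <- tibble::tibble(
    chrom = "chrS",
    start = params$boundaries$bin * res,
    end = (params$boundaries$bin + 1L) * res,
    bin = params$boundaries$bin,
    attenuation = params$boundaries$attenuation
  )
  truth <- structure(
    list(params = params, expected = e, loops = truth_loops,
         boundaries = truth_boundaries, compartments = params$compartments),
    class = "synthetic_truth"
  )
  list(matrix = contact_matrix(counts, chrom = "chrS", resolution = res),
       truth = truth)
}

#' Simulate a compartment phasing track
#'
#' Encodes the planted compartment labels as +1 (A) / -1 (B) plus Gaussian
#' noise, emulating a GC%-like phasing track. With `noise_sd = 0` the track
#' correlates perfectly with the labels; otherwise the expected Pearson
#' correlation is `1 / sqrt(1 + noise_sd^2)`.
#'
#' @param params A [sim_params()] with non-NULL `compartments`.
#' @param noise_sd Noise standard deviation (label encoding has unit scale).
#' @param seed Seed; defaults to a sub-stream of `params$seed`.
#' @return A track tibble `chrom`, `start`, `end`, `value` (one row per
#'   bin).
#' @export
simulate_phasing_track <- function(params, noise_sd = 0,
                                   seed = derive_seed(params$seed, 101L)) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(params$compartments)) {
    stop("params has no compartment labels")
  }
  enc <- ifelse(params$compartments == "A", 1, -1)
  val <- enc + local_seed(seed, rnorm(params$n_bins, 0, noise_sd))
  n <- params$n_bins
  tibble::tibble(
    chrom = "chrS",
    start = (seq_len(n) - 1L) * params$resolution,
    end = seq_len(n) * params$resolution,
    value = val
  )
}

#' Reverse complement of DNA strings
#' @param x Character vector over A, C, G, T, N.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' A sharp synthetic CTCF-like PWM
#'
#' High-information motif used as the default planted motif: each column
#' gives probability `consensus_prob` to the consensus base and splits the
#' remainder evenly. With `consensus_prob = 0.94` a motif sampled from the
#' columns stays above the 80% relative-score threshold in about 97% of
#' draws (at most `floor(0.2 * width)` sampled mismatches are tolerated).
#'
#' @param consensus Consensus sequence (default a 12-mer CTCF-core-like
#'   sequence chosen to be strongly non-self-complementary, so motif
#'   orientation is well defined).
#' @param consensus_prob Probability of the consensus base per column.
#' @return A [pwm()].
#' @export
default_pwm <- function(consensus = "CCAGCAGAGGGC", consensus_prob = 0.94) {
  bases <- strsplit(consensus, "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  w <- length(bases)
  counts <- matrix((1 - consensus_prob) / 3 * 1000, 4, w,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_len(w)) counts[bases[k], k] <- consensus_prob * 1000
  pwm(counts, pseudocount = 0, name = "synthetic_ctcf_core")
}

#' Simulate a genome, peaks with planted motifs, and replicate signals
#'
#' Generates a uniform-random background sequence, places `n_peaks`
#' equally spaced peaks on it, inserts a PWM-derived motif at the summit of
#' a fraction of peaks on a random strand, and attaches per-replicate
#' signal values: reference replicates draw
#' `base_signal * exp(N(0, noise_sd))`; alternate replicates are further
#' multiplied by the condition fold change of the peak's truth class
#' (`gain` = `fold_gain`, `loss` = `fold_loss`, `stable` = 1).
#'
#' @param n_peaks Number of peaks.
#' @param genome_length Genome length in bp.
#' @param pwm_obj Planted motif ([pwm()]); must fit inside a peak.
#' @param planted_fraction Fraction of peaks receiving a motif.
#' @param replicates Replicates per condition.
#' @param fold_gain,fold_loss Condition fold changes of the gain/loss truth
#'   classes.
#' @param class_fractions Named fractions for `gain`, `loss`, `stable`.
#' @param noise_sd Lognormal signal noise sd (0 = noiseless).
#' @param base_signal Baseline signal level.
#' @param peak_width Peak width in bp.
#' @param motif_mode `"sample"` draws each motif base from the PWM columns;
#'   `"consensus"` inserts the consensus.
#' @param seed Integer seed.
#' @return A list: `genome` (named character), `peaks` (tibble with
#'   coordinates, `summit`, truth `class`, `planted`, `motif_strand` and
#'   signal columns `ref_1..`, `alt_1..`), and `pwm_obj`.
#' @export
simulate_peaks_and_genome <- function(n_peaks = 200L, genome_length = 200000L,
                                      pwm_obj = default_pwm(),
                                      planted_fraction = 1,
                                      replicates = 2L,
                                      fold_gain = 2, fold_loss = 0.5,
                                      class_fractions = c(gain = 0.25,
                                                          loss = 0.25,
                                                          stable = 0.5),
                                      noise_sd = 0.1, base_signal = 10,
                                      peak_width = 400L,
                                      motif_mode = c("sample", "consensus"),
                                      seed = 1L) {
  motif_mode <- match.arg(motif_mode)
  stopifnot(planted_fraction >= 0, planted_fraction <= 1, replicates >= 1)
  w <- pwm_obj$width
  if (w > peak_width) stop("motif wider than peak")
  spacing <- genome_length %/% (n_peaks + 1L)
  if (spacing <= peak_width) stop("genome too short for the requested peaks")

  local_seed(seed, {
    genome <- paste(sample(c("A", "C", "G", "T"), genome_length,
                           replace = TRUE), collapse = "")
    summits <- spacing * seq_len(n_peaks)
    planted <- seq_len(n_peaks) %in%
      sample(n_peaks, round(planted_fraction * n_peaks))
    strands <- ifelse(runif(n_peaks) < 0.5, "+", "-")
    classes <- sample(names(class_fractions), n_peaks, replace = TRUE,
                      prob = class_fractions)
    chars <- strsplit(genome, "")[[1]]
    for (p in which(planted)) {
      motif <- if (motif_mode == "consensus") pwm_consensus(pwm_obj) else
        paste(vapply(seq_len(w), function(k) {
          sample(rownames(pwm_obj$prob), 1, prob = pwm_obj$prob[, k])
        }, character(1)), collapse = "")
      if (strands[p] == "-") motif <- revcomp(motif)
      at <- summits[p] - w %/% 2L  # 0-based insert position
      chars[(at + 1L):(at + w)] <- strsplit(motif, "")[[1]]
    }
    genome <- paste(chars, collapse = "")
    fold <- c(gain = fold_gain, loss = fold_loss, stable = 1)[classes]
    peaks <- tibble::tibble(
      chrom = "chrS",
      start = as.integer(summits - peak_width %/% 2L),
      end = as.integer(summits + peak_width %/% 2L),
      name = sprintf("peak_%d", seq_len(n_peaks)),
      summit = as.integer(summits),
      class = classes,
      planted = planted,
      motif_strand = ifelse(planted, strands, NA_character_)
    )
    for (r in seq_len(replicates)) {
      peaks[[sprintf("ref_%d", r)]] <-
        base_signal * exp(rnorm(n_peaks, 0, noise_sd))
      peaks[[sprintf("alt_%d", r)]] <-
        base_signal * unname(fold) * exp(rnorm(n_peaks, 0, noise_sd))
    }
    list(genome = c(chrS = genome), peaks = peaks, pwm_obj = pwm_obj)
  })
}

#' Place random non-colliding loop centroids
#'
#' Samples `n` loop centroids with anchor separations in
#' `[min_offset, max_offset]` bins, at least `margin` bins from the matrix
#' edges, and pairwise Chebyshev-separated by at least `min_gap` bins so
#' that scoring windows and donuts of distinct loops do not collide.
#'
#' @param n Number of loops.
#' @param n_bins Matrix size in bins.
#' @param min_offset,max_offset Range of `bin_j - bin_i`.
#' @param margin Edge margin in bins.
#' @param min_gap Minimum Chebyshev distance between centroids.
#' @param seed Integer seed.
#' @return Tibble with `bin_i`, `bin_j`.
#' @export
plant_loops <- function(n, n_bins, min_offset = 15L, max_offset = 60L,
                        margin = 20L, min_gap = 14L, seed = 1L) {
  local_seed(seed, {
    got_i <- integer(0)
    got_j <- integer(0)
    tries <- 0L
    while (length(got_i) < n && tries < 500L * n) {
      tries <- tries + 1L
      off <- sample(min_offset:max_offset, 1)
      hi <- n_bins - margin - off - 1L
      if (hi < margin) next
      bi <- if (hi == margin) margin else sample(margin:hi, 1)
      bj <- bi + off
      if (length(got_i) == 0L ||
          all(pmax(abs(got_i - bi), abs(got_j - bj)) >= min_gap)) {
        got_i <- c(got_i, bi)
        got_j <- c(got_j, bj)
      }
    }
    if (length(got_i) < n) stop("could not place ", n, " loops; matrix too small")
    tibble::tibble(bin_i = as.integer(got_i), bin_j = as.integer(got_j))
  })
}

#' Simulate a replicated two-condition loop experiment
#'
#' Builds matched reference (wild-type-like) and alternate (mutant-like)
#' contact maps sharing one planted loop set: `n_diff` loops have amplitude
#' `amp_ref` in the reference condition and `amp_alt` in the alternate;
#' `n_stable` loops keep `amp_ref` in both. Each replicate is an independent
#' Poisson draw from its condition's expected map, with per-sample seeds
#' derived from `seed`.
#'
#' @param n_ref,n_alt Replicates per condition.
#' @param n_diff,n_stable Numbers of differential and stable planted loops.
#' @param amp_ref,amp_alt Loop amplitudes (reference; alternate for the
#'   differential set).
#' @param spread Loop bump sd in bins.
#' @param n_bins,depth,alpha Passed to [sim_params()].
#' @param seed Integer seed.
#' @return A list: `samples` (named list of raw [contact_matrix()],
#'   `ref_1.. alt_1..`), `loops` (planted loop tibble with truth `class`),
#'   `ref_params`, `alt_params`.
#' @export
simulate_differential_experiment <- function(n_ref = 2L, n_alt = 2L,
                                             n_diff = 40L, n_stable = 40L,
                                             amp_ref = 4, amp_alt = 2,
                                             spread = 1, n_bins = 600L,
                                             depth = 2e6, alpha = 1,
                                             seed = 1L) {
  pos <- plant_loops(n_diff + n_stable, n_bins, seed = derive_seed(seed, 1L))
  cls <- rep(c("differential", "stable"), c(n_diff, n_stable))
  ref_loops <- tibble::tibble(bin_i = pos$bin_i, bin_j = pos$bin_j,
                              amplitude = amp_ref, spread = spread)
  alt_loops <- ref_loops
  alt_loops$amplitude[cls == "differential"] <- amp_alt

  samples <- list()
  for (r in seq_len(n_ref)) {
    p <- sim_params(n_bins = n_bins, alpha = alpha, loops = ref_loops,
                    depth = depth, seed = derive_seed(seed, 10L + r))
    samples[[sprintf("ref_%d", r)]] <- simulate_contact_map(p)$matrix
  }
  for (r in seq_len(n_alt)) {
    p <- sim_params(n_bins = n_bins, alpha = alpha, loops = alt_loops,
                    depth = depth, seed = derive_seed(seed, 20L + r))
    samples[[sprintf("alt_%d", r)]] <- simulate_contact_map(p)$matrix
  }
  loops <- tibble::tibble(
    chrom = "chrS",
    start5 = pos$bin_i * 10000L, end5 = (pos$bin_i + 1L) * 10000L,
    start3 = pos$bin_j * 10000L, end3 = (pos$bin_j + 1L) * 10000L,
    bin_i = pos$bin_i, bin_j = pos$bin_j, class = cls
  )
  list(samples = samples, loops = loops,
       ref_params = ref_loops, alt_params = alt_loops)
}
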