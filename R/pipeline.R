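# End-to-end orchestration: simulate -> balance -> score -> differential ->
# insulation -> compartments, from a serializable YAML/list configuration,
# with a deterministic run manifest (inputs, parameters, checksums, counts).

default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    outdir = "loopscape_run",
    simulate = list(enabled = TRUE, n_bins = 200L, resolution = 10000L,
                    depth = 1e6, alpha = 1, n_loops = 10L, amplitude = 4,
                    spread = 1, n_boundaries = 0L, attenuation = 0.2,
                    compartment_block = 0L, compartment_affinity = 0.5,
                    replicates = 1L, mutant_amplitude = NULL),
    balance = list(enabled = TRUE, tol = 1e-5, max_iter = 200L),
    loopscore = list(enabled = TRUE, loops = NULL, n_samples = 15L,
                     ring_radius = 8L),
    diffloops = list(enabled = FALSE),
    insulation = list(enabled = FALSE, s = 3L, d = 5L, threshold = 0.75,
                      min_run = 3L),
    compartments = list(enabled = FALSE, n_q = 20L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML file (or takes a list) and fills unset keys with the
#' documented defaults. The configuration is fully serializable; a run
#' re-executed from its persisted configuration reproduces all outputs.
#'
#' @param config Path to a YAML file or a named list.
#' @return A complete configuration list.
#' @export
read_run_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(user))
  merge_config(default_config(), user)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic input:
#' `simulate` draws raw contact maps (one wild-type-like condition, plus a
#' mutant-like condition when `mutant_amplitude` is set) and writes matrix
#' triplets and truth files; `balance` IPF-normalizes every sample;
#' `loopscore` scores the truth (or a supplied) loop list per sample;
#' `diffloops` makes consistency-based differential calls between the two
#' conditions; `insulation` and `compartments` run on the first reference
#' sample. All randomness derives from the single `seed` via
#' [derive_seed()]. A JSON manifest records the configuration, per-stage
#' outputs with md5 checksums, and element counts; it contains no
#' timestamps, so identical configurations yield identical manifests.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [read_run_config()]).
#' @param outdir Output directory override.
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "loopscape",
                   version = as.character(utils::packageVersion("loopscape")),
                   config = cfg, stages = list())
  outfile <- function(...) file.path(cfg$outdir, paste0(...))
  checksum <- function(paths) {
    as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  }

  samples <- list()   # raw contact matrices by sample id
  truth_loops <- NULL
  phasing <- NULL

  if (isTRUE(cfg$simulate$enabled)) {
    sc <- cfg$simulate
    pos <- if (sc$n_loops > 0) {
      plant_loops(sc$n_loops, sc$n_bins,
                  max_offset = max(16L, min(60L, sc$n_bins %/% 2L)),
                  margin = min(20L, max(12L, sc$n_bins %/% 6L)),
                  min_gap = min(14L, max(6L, sc$n_bins %/% 8L)),
                  seed = derive_seed(cfg$seed, 1L))
    } else {
      tibble::tibble(bin_i = integer(), bin_j = integer())
    }
    boundaries <- if (sc$n_boundaries > 0) {
      tibble::tibble(
        bin = as.integer(round(seq(sc$n_bins * 0.2, sc$n_bins * 0.8,
                                   length.out = sc$n_boundaries))),
        attenuation = sc$attenuation
      )
    } else NULL
    labels <- if (sc$compartment_block > 0) {
      rep(c("A", "B"),
          each = sc$compartment_block,
          length.out = sc$n_bins)
    } else NULL
    build <- function(amp, seed) {
      sim_params(
        n_bins = sc$n_bins, resolution = sc$resolution, alpha = sc$alpha,
        loops = if (nrow(pos)) tibble::tibble(bin_i = pos$bin_i,
                                              bin_j = pos$bin_j,
                                              amplitude = amp,
                                              spread = sc$spread)
                else NULL,
        boundaries = boundaries, compartments = labels,
        compartment_affinity = sc$compartment_affinity,
        depth = sc$depth, seed = seed
      )
    }
    files <- character(0)
    conds <- list(ref = sc$amplitude)
    if (!is.null(sc$mutant_amplitude)) conds$alt <- sc$mutant_amplitude
    for (cond in names(conds)) {
      for (r in seq_len(sc$replicates)) {
        id <- sprintf("%s_%d", cond, r)
        p <- build(conds[[cond]],
                   derive_seed(cfg$seed, match(cond, names(conds)) * 100L + r))
        sim <- simulate_contact_map(p)
        samples[[id]] <- sim$matrix
        f <- outfile(id, ".matrix.tsv")
        write_contact_matrix(sim$matrix, f, bins = outfile(id, ".bins.tsv"))
        files <- c(files, f, outfile(id, ".bins.tsv"))
        if (is.null(truth_loops)) {
          truth_loops <- sim$truth$loops
          write_bedpe(truth_loops, outfile("truth_loops.bedpe"))
          readr::write_tsv(sim$truth$boundaries,
                           outfile("truth_boundaries.bed"),
                           col_names = FALSE, progress = FALSE)
          files <- c(files, outfile("truth_loops.bedpe"),
                     outfile("truth_boundaries.bed"))
        }
      }
    }
    if (!is.null(labels)) {
      p0 <- build(conds$ref, cfg$seed)
      phasing <- simulate_phasing_track(p0, noise_sd = 0,
                                        seed = derive_seed(cfg$seed, 999L))
      write_bedgraph(phasing, outfile("phasing.bedgraph"))
      files <- c(files, outfile("phasing.bedgraph"))
    }
    manifest$stages$simulate <- list(
      n_samples = length(samples), n_loops = nrow(truth_loops %||% tibble::tibble()),
      outputs = checksum(files)
    )
  }

  balanced <- list()
  if (isTRUE(cfg$balance$enabled)) {
    if (!length(samples)) stop("balance: matrix (no simulated samples)")
    files <- character(0)
    for (id in names(samples)) {
      bm <- ipf_balance(samples[[id]], tol = cfg$balance$tol,
                        max_iter = cfg$balance$max_iter)
      balanced[[id]] <- bm
      f <- outfile(id, ".norm.tsv")
      write_contact_matrix(bm, f)
      write_weights(bm, outfile(id, ".weights.tsv"))
      files <- c(files, f, outfile(id, ".weights.tsv"))
    }
    manifest$stages$balance <- list(
      n_samples = length(balanced),
      converged = all(purrr::map_lgl(balanced, "converged")),
      outputs = checksum(files)
    )
  }

  quants <- NULL
  if (isTRUE(cfg$loopscore$enabled)) {
    if (!length(balanced)) stop("loopscore: balanced matrix")
    loops <- if (!is.null(cfg$loopscore$loops)) {
      if (!file.exists(cfg$loopscore$loops)) {
        stop("loopscore: loops (missing file ", cfg$loopscore$loops, ")")
      }
      read_bedpe(cfg$loopscore$loops,
                 resolution = balanced[[1]]$resolution)
    } else if (!is.null(truth_loops)) {
      truth_loops
    } else {
      stop("loopscore: loops (no loop list available)")
    }
    quants <- purrr::map_dfr(names(balanced), function(id) {
      score_loops(loops, balanced[[id]], seed = cfg$seed,
                  n_samples = cfg$loopscore$n_samples,
                  ring_radius = cfg$loopscore$ring_radius) |>
        dplyr::mutate(sample = id, .before = 1)
    })
    f <- outfile("loop_quants.tsv")
    readr::write_tsv(dplyr::select(quants, -dplyr::any_of("change_frac")),
                     f, progress = FALSE)
    manifest$stages$loopscore <- list(
      n_loops_scored = sum(quants$scoreable), outputs = checksum(f)
    )
  }

  if (isTRUE(cfg$diffloops$enabled)) {
    if (is.null(quants)) stop("diffloops: loop quantifications")
    ref_ids <- grep("^ref_", names(balanced), value = TRUE)
    alt_ids <- grep("^alt_", names(balanced), value = TRUE)
    if (!length(alt_ids)) stop("diffloops: alt samples (enable mutant_amplitude)")
    calls <- condition_specific_loops(quants, ref_ids, alt_ids)
    f <- outfile("diff_loops.tsv")
    readr::write_tsv(calls, f, progress = FALSE)
    manifest$stages$diffloops <- list(
      n_weakened = sum(calls$call == "weakened"),
      n_strengthened = sum(calls$call == "strengthened"),
      outputs = checksum(f)
    )
  }

  if (isTRUE(cfg$insulation$enabled)) {
    if (!length(balanced)) stop("insulation: balanced matrix")
    tr <- insulation_track(balanced[[1]], s = cfg$insulation$s,
                           d = cfg$insulation$d)
    pk <- insulation_peaks(tr, threshold = cfg$insulation$threshold,
                           min_run = cfg$insulation$min_run)
    f1 <- outfile("insulation.bedgraph")
    write_bedgraph(dplyr::transmute(tr, chrom = .data$chrom,
                                    start = .data$start, end = .data$end,
                                    value = .data$score) |>
                     dplyr::filter(!is.na(.data$value)), f1)
    f2 <- outfile("insulation_peaks.tsv")
    readr::write_tsv(pk, f2, progress = FALSE)
    manifest$stages$insulation <- list(n_peaks = nrow(pk),
                                       outputs = checksum(c(f1, f2)))
  }

  if (isTRUE(cfg$compartments$enabled)) {
    if (!length(balanced)) stop("compartments: balanced matrix")
    if (is.null(phasing)) stop("compartments: phasing track (set compartment_block)")
    res <- compartment_eigenvector(balanced[[1]], phasing)
    res <- saddle(balanced[[1]], res, n_q = cfg$compartments$n_q)
    f1 <- outfile("eigenvector.bedgraph")
    write_bedgraph(tidy(res) |>
                     dplyr::filter(!is.na(.data$eigenvector)) |>
                     dplyr::transmute(chrom = .data$chrom,
                                      start = .data$start, end = .data$end,
                                      value = .data$eigenvector), f1)
    f2 <- outfile("saddle.tsv")
    readr::write_tsv(tibble::as_tibble(res$saddle, .name_repair = "minimal"),
                     f2, col_names = FALSE, progress = FALSE)
    manifest$stages$compartments <- list(
      chosen_index = res$chosen_index,
      correlation_with_phasing = res$correlation_with_phasing,
      outputs = checksum(c(f1, f2))
    )
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
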