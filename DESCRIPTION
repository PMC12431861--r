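Package: loopscape
Title: Quantification of Chromatin Loops, Insulators and CTCF Occupancy from Hi-C and ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify chromatin architecture from binned Hi-C contact
    matrices and ChIP-seq style peak data: iterative-proportional-fit matrix
    balancing and distance-decay summaries, per-loop scoring against a randomly
    sampled donut background with aggregate peak analysis (APA), consistency
    based differential loop calls between conditions, insulation-score tracks
    with peak calling and per-peak differential insulation, A/B compartment
    eigenvector selection with saddle construction, position-weight-matrix
    scanning with summit-window motif orientation, congruent-change differential
    peak calls, and enhancer/promoter/loop-domain interval annotation. A fully
    seeded synthetic-data generator (power-law distance decay, multiplicative
    bin biases, Poisson counting noise, planted loops, boundaries, compartments,
    motifs and replicate fold changes) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
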