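---
title: "Models and methods behind loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

loopscape quantifies chromatin architecture — loops, insulators,
compartments, and CTCF occupancy — from binned intra-chromosomal Hi-C
matrices and peak/coverage data. This vignette explains each model, the
parameters that matter, the numerical conventions, and what the bundled
synthetic-data generator does and does not emulate.

## Coordinate and container conventions

Everything genomic is 0-based, half-open (BED dialect); bin ids are
0-based; `to_one_based()`/`to_zero_based()` form the single conversion
layer for 1-based dialects. Tabular data (loops, peaks, tracks, scores)
are tibbles, so results chain with the pipe; the contact map is the one
non-tabular object, an S3 `contact_matrix` holding a dense symmetric
matrix, its resolution, and a per-bin validity mask. Bins with zero raw
marginal are treated as unmappable: no mappability track is assumed, so
the zero-marginal rule is our masking convention, and masked rows/columns
are excluded from every statistic rather than silently zeroed into them.

## Matrix balancing

`ipf_balance()` removes multiplicative per-bin biases by iterative
proportional fitting. We use a *symmetric* Sinkhorn-style variant — a
single weight vector applied to rows and columns, updated as
`w ← w · sqrt(target/marginal)` — because it preserves matrix symmetry at
every iteration, whereas alternating row/column fits only restore
symmetry in the limit. Convergence is declared when the coefficient of
variation of valid-bin marginals falls below `tol` (default `1e-5`,
`max_iter = 200`; both are exposed, and the bias-cancellation check in
`scripts/acceptance.R` runs at `1e-12` to demonstrate convergence to
machine precision). The target marginal is the *mean raw marginal*, a
scale-preserving choice: normalized values from samples sequenced to
similar depth stay numerically comparable, which the cross-sample loop
comparisons assume. Balancing a balanced matrix is a no-op up to `tol`.

`distance_decay()` summarizes each off-diagonal by its median normalized
value, per chromosome, with a cross-chromosome median-of-medians and a
configurable exclusion list (real datasets occasionally carry one
chromosome with library-specific artefacts that should not enter the
summary).

## Loop scoring

The loop signal is the mean (and the loop strength the sum) of the 5×5
pixel window at the loop centroid — the bin pair containing the two
anchor midpoints. The local background is estimated from the *donut*
around the centroid. The three published donut numbers (19×19 outer
square, 9×9 exclusion, 5×5 squares "at a distance of 8 pixels") are
mutually inconsistent — a 5×5 square centered 8 bins away reaches 10 bins
out. We honor the explicit distance: candidate square centers are all 64
offsets on the Chebyshev ring of radius 8 (`donut_ring_offsets()`),
accepting a 1-bin overhang beyond the nominal 19×19; the ring radius is a
parameter. Candidates whose square leaves the matrix or touches the
diagonal (any cell with row ≥ column) are excluded, 15 are drawn
uniformly *without replacement* (all survivors are used when fewer
remain), and the background is the mean of per-square means. Whether the
original procedure sampled with or without replacement, or allowed
diagonal-crossing squares, is unstated; both choices are pinned here and
tested.

`LS = log2((signal + ε)/(background + ε))` with `ε = 1e-9` guarding a
zero background (whether the original analysis used a pseudocount is
unstated; at real signal levels `ε` is numerically invisible). Loops
whose windows leave the matrix are flagged unscoreable, never dropped
silently. Each loop's sampling uses an RNG stream derived from the global
seed and its centroid bins (`derive_seed()`), so scores are independent
of loop-list order and reproducible across samples — condition
comparisons must score every sample with the same loop list and seed so
that the same donut squares are read in each sample.

Architectural loops require `LS > 1` (strictly) *and* convergent motifs:
at least one forward-oriented CTCF motif peak overlapping the 5′ anchor
and a reverse-oriented one overlapping the 3′ anchor. APA averages 21×21
windows (the half-width is a parameter; the window size follows the
established APA convention since the source does not state one) over
loops spanning more than 100 kb, and scores the center pixel against the
lower-left 6×6 corner. APA windows this size are only meaningful for
loops at least ~27 bins from the diagonal: closer than that, the
short-distance corner of the window exceeds even a four-fold focal
enrichment simply through distance decay.

## Differential loops

`condition_specific_loops()` implements the replicate-consistency rule:
a loop is weakened when *every* reference-vs-alternate pair shows
strictly higher strength *and* strictly higher LS in the reference
(strengthened is the mirror; ties break consistency). "Consistently
higher" is read as strict inequality.

A property worth knowing: with two replicates per condition, a truly
stable loop passes an all-pairs strict-consistency test on one statistic
by chance with probability 1/6 per direction (the two reference values
must occupy the top two ranks of four exchangeable values). Because LS
and strength share their numerator, the LS gate is strongly correlated
with the strength gate and removes only part of that chance rate: the
acceptance battery measures a false-call rate of roughly 0.1–0.3 among
planted stable loops at 2+2 replicates, while sensitivity for a
two-fold amplitude change at depth 2×10⁶ is essentially 1. The rule is
faithful to its published form; users needing a lower false-call rate
should add replicates or an effect-size threshold rather than reading
the consistency call as an error-controlled test.

## Insulation

The insulation score is reconstructed from the stated square geometry
(the original defers its formula to earlier work): on the
expected-normalized matrix, `U`, `D` and `X` are means of s×s squares
(`s = 3`) centered at `(i−d, i−d)`, `(i+d, i+d)` and `(i−d, i+d)`, and
`IS(i) = log2(((U+D)/2 + ε)/(X + ε))`. With `d = 5` the cross square sits
`2d = 10` bins off the diagonal, matching the stated "10 bins from the
diagonal"; the alternative reading (`d = 10`) is available through the
parameter. Expected-normalization makes a featureless matrix score ≈ 0,
which is what renders the fixed 0.75 threshold meaningful. The score is
missing within `d + ⌊s/2⌋` bins of the matrix ends and wherever a square
touches a masked bin; missing bins break peak runs.

Insulation peaks are maximal runs of ≥ 3 consecutive bins with
`IS > 0.75` (strict). A sharp insulator produces a *plateau* of nearly
tied scores roughly `±(d − 1 + ⌊s/2⌋)` bins wide, so the reported summit
(maximum, leftmost on ties) can sit a few bins left of the true boundary;
the run midpoint is the better locator and is what the recovery checks
use. Differential insulation is the per-peak mean of `IS_ref − IS_alt`
over bins defined in both tracks.

## Compartments

`compartment_eigenvector()` follows the pipeline: expected-normalize →
Pearson correlation matrix over valid bins → first three eigenvectors →
select the one with the highest |Pearson r| against a phasing track
(GC% or gene density in real data) → orient so the correlation is
positive, making positive values the A compartment. Whether the original
PCA acted on the correlation of the observed/expected map or on the raw
normalized map is not fully explicit; our order is stated and the
observed/expected transform is exposed as `oe_matrix()`. Compartments
here consume IPF-balanced matrices rather than the Knight–Ruiz-balanced
matrices of the source's external tooling — a documented deviation that
is immaterial on synthetic data, where eigenvector sign structure is
robust to the balancing variant. The saddle assigns valid bins to `n_q`
equal-occupancy eigenvector quantiles (default 50; 20 in the compact
test scenes; the source does not state its count) and averages
observed/expected over quantile pairs, excluding the diagonal.

## Motifs and peaks

`pwm_scan()` scores every window on both strands with
`raw = Σ log(p_base/background_base)`; `N` scores as background
(contribution 0). The relative score rescales raw between the motif's
attainable minimum and maximum, matching the "min.score" percentage
convention of PWM hit counting, with 0.8 as the default threshold.
`best_motif_at_peak()` scans the 50-bp window centered at the summit and
keeps the single highest-raw-score hit — ties break to the leftmost
position, then the + strand — which sets the peak's motif orientation.
Scanner correctness is established against an exhaustive brute-force
scorer, and forward hit counts are cross-checked against
`Biostrings::countPWM` at the same threshold.

`peak_signal()` summarizes coverage as either the AUC over summit ±100 bp
(uncovered bases count 0) or the mean over summit ±50 bp (uncovered bases
excluded). The congruent-change rule classifies a peak as gained/lost
only when *every* replicate pair changes by at least 25% in the same
direction; "altered by at least 25%" is read symmetrically in the change
fraction, i.e. ratio ≥ 1.25 for gains and ≤ 0.75 for losses, with a zero
reference and positive alternate counting as gain. This is the
replicate-agreement rule alone; count-based statistical testing of
occupancy (e.g. negative-binomial models) is outside this package's
scope and should be layered on top where error control is needed.

Enhancers are ATAC peaks overlapping H3K27ac regions outside ±500-bp TSS
promoters; peak-to-gene annotation uses ±3-kb promoter windows; each gene
is assigned the smallest loop domain (anchor-midpoint span, leftmost on
exact ties) containing its promoter, and enhancers are counted in the two
500-kb flanks outside the domain ends (an enhancer overlapping both
flanks counts once per flank).

## The synthetic-data generator

`simulate_contact_map()` builds an expected map
`e_ij = A(|i−j|+1)^{−α}` × boundary attenuations (γ for pairs straddling
a boundary bin) × isotropic Gaussian loop bumps
(`1 + (λ−1)·exp(−(Δi²+Δj²)/2σ²)`, mirrored for symmetry) × compartment
affinity (ρ for cross-compartment pairs) × per-bin biases `b_i b_j`,
rescaled so the upper-triangle total equals `depth`, then draws Poisson
counts. Defaults: α = 1 (the classic contact-probability decay), loop
amplitudes λ = 4 (reference) vs 2 (perturbed) with σ = 1 bin — matching
the 5×5 focal-enrichment scale the scoring assumes — boundary
attenuation γ = 0.2 for clearly insulating boundaries, compartment
affinity ρ = 0.5, and depths of 1–2×10⁶ contacts per 200–600-bin
chromosome, which put per-cell counts in the tens — deep enough for the
statistics to be well-defined, shallow enough that Poisson noise is
visible. Problem sizes in the test scenes (200–600 bins, 40+40 planted
loops, 4 boundaries, 2+2 replicates) were chosen as the smallest at
which each recovery property is comfortably expressed.

`simulate_phasing_track()` encodes planted labels as ±1 plus Gaussian
noise (expected |r| = 1/√(1+σ²)). `simulate_peaks_and_genome()` plants a
PWM-derived motif at a fraction of peak summits on random strands and
attaches lognormal replicate signals with per-class fold changes. The
default planted motif (`default_pwm()`) is a sharp 12-mer with 0.94
consensus probability per column: at the 80% relative-score threshold a
sampled motif tolerates ⌊0.2·12⌋ = 2 mismatches, and
P(Binom(12, 0.06) ≤ 2) ≈ 0.97, so near-complete recovery is expected by
construction. Its consensus was chosen to be strongly
non-self-complementary (Hamming distance 10 to its own reverse
complement), because orientation is only well defined for asymmetric
motifs — CTCF's true motif is strongly asymmetric.

What the generator does *not* emulate: over-dispersed (beyond-Poisson)
counts, translocation/copy-number artefacts, mappability structure,
nested TADs or loop anchors shared by several loops, inter-chromosomal
contacts, fragment-level or read-level structure, and realistic
sequencing depths. Passing the recovery suite therefore demonstrates the
correctness of the estimators under the stated generative model, not
their robustness to every artefact of real libraries.

## The pipeline runner

`run_pipeline()` executes simulate → balance → loopscore → diffloops →
insulation → compartments from a YAML (or list) configuration. All
randomness flows from the single `seed` via `derive_seed()`; the JSON
manifest records parameters, per-output md5 checksums and element counts,
and contains no timestamps, so a rerun of the same configuration yields a
byte-identical manifest. A stage whose input is missing fails with a
message naming the stage and the missing artefact.
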