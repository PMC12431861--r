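# loopscape

Quantification of chromatin architecture from binned Hi-C contact matrices
and ChIP-seq-style peak data: matrix balancing, per-loop scoring against a
sampled local background, consistency-based differential loop calls,
insulation-score peaks, A/B compartment saddles, CTCF motif orientation at
peak summits, congruent-change differential peaks, and
enhancer/promoter/loop-domain interval annotation — together with a fully
seeded synthetic-data generator, so that every stage can be exercised and
validated without any external download.

## Who this is for

Researchers in 3D genome biology who have (i) intra-chromosomal contact
matrices at a fixed resolution (10 kb by default), (ii) loop lists
(BEDPE), peak lists with summits (BED/narrowPeak), coverage tracks
(bedGraph), genome sequence (FASTA) and motif models (JASPAR PFM), and who
want reproducible, scriptable answers to questions like: *which loops are
architectural? which loops and insulators weaken in a mutant? where do
compartments sit, and how strong is their segregation? which CTCF peaks
change occupancy, and how are they oriented at loop anchors?*

## The statistics implemented

* **IPF balancing.** Iterative proportional fit with a symmetric
  Sinkhorn-style update: a single per-bin weight vector `w` with
  `normalized[i,j] = raw[i,j] · w_i · w_j`, iterated as
  `w ← w · sqrt(target / marginal)` until the coefficient of variation of
  the valid-bin marginals drops below tolerance. The target marginal is
  the mean raw marginal, so the overall scale is preserved.
* **Loop score (LS).** For a loop with centroid pixel `(i, j)`,
  `LS = log2( mean(5×5 window at (i,j)) / background )`, where the
  background is the mean of 15 randomly drawn 5×5 squares whose centers
  lie on the Chebyshev ring at distance 8 from the centroid (the donut),
  sampled without replacement and excluding squares that leave the matrix
  or cross the diagonal. Architectural loops are those with `LS > 1` and
  convergent CTCF motifs: a forward motif on the 5′ anchor and a reverse
  motif on the 3′ anchor.
* **APA.** The element-wise mean of 21×21 windows centered on the
  centroids of loops spanning > 100 kb; the APA score is the center pixel
  over the mean of the lower-left 6×6 (short-distance) corner.
* **Differential loops.** A loop is called weakened (or strengthened)
  when, in *every* reference-versus-alternate sample pair, both the loop
  strength (5×5 sum) and the LS are strictly higher in the same
  condition.
* **Insulation score.** `IS(i) = log2( ((U + D)/2) / X )` on the
  expected-normalized matrix, with `U`, `D`, `X` the means of 3×3 squares
  at `(i−d, i−d)`, `(i+d, i+d)` and `(i−d, i+d)` (`d = 5`, so the cross
  square sits 10 bins off the diagonal). Insulation peaks are runs of
  ≥ 3 consecutive bins with `IS > 0.75`; differential insulation is the
  per-peak mean of `IS_ref − IS_alt`.
* **Compartments.** First three eigenvectors of the Pearson correlation
  matrix of the observed/expected map; the one best correlated (absolute
  Pearson r) with a phasing track is chosen and oriented positive-with-
  phasing; the saddle averages observed/expected over eigenvector
  quantile pairs (upper-left = B–B, lower-right = A–A).
* **Motifs and peaks.** PWM scanning with
  `raw = Σ log(p_base / background)` and min–max relative scores (80%
  threshold by default); the best hit in the 50-bp summit window sets a
  peak's motif orientation. Differential peaks follow the congruent
  ≥ 25% rule: every replicate pair must change in the same direction by
  at least 25%. Enhancers are open-chromatin peaks overlapping H3K27ac
  regions outside ±500-bp promoters; genes are assigned the smallest loop
  domain containing their promoter, and enhancers are counted in the two
  500-kb domain flanks.

## Worked example

Simulate one chromosome (300 bins at 10 kb, 2 million contacts) with
three planted loops and one insulating boundary, balance it, and
quantify:

```r
library(loopscape)
library(dplyr)

params <- sim_params(
  n_bins = 300, resolution = 10000, depth = 2e6, seed = 7,
  loops = tibble(bin_i = c(40, 120, 210), bin_j = c(75, 160, 250),
                 amplitude = 8, spread = 2),
  boundaries = tibble(bin = 150, attenuation = 0.2)
)
sim <- simulate_contact_map(params)
bm  <- ipf_balance(sim$matrix)
glance(bm)
#>   chrom n_bins n_valid n_iterations converged marginal_cv
#> 1 chrS     300     300           12 TRUE       0.00000678

score_loops(sim$truth$loops, bm, seed = 7) |>
  select(bin_i, bin_j, signal_mean, strength_sum, background, ls)
#>   bin_i bin_j signal_mean strength_sum background    ls
#> 1    40    75       177.         4417.       43.6  2.02
#> 2   120   160        35.5         887.       10.9  1.71
#> 3   210   250       158.         3953.       35.2  2.17

apa(sim$truth$loops, bm)
#> <apa_result> 3 loops, 21x21 window, APA score 3.862

insulation_peaks(insulation_track(bm))
#>   chrom start_bin end_bin n_bins mean_is summit_bin
#> 1 chrS        146     154      9    1.98        148
```

All three planted loops score well above the architectural `LS > 1`
threshold (their centroid signal is 3–4.5× the local donut background),
the aggregate APA score of 3.9 reflects the strong focal enrichment, and
the single planted boundary at bin 150 is recovered as an insulation peak
spanning bins 146–154. `autoplot()` draws the APA and saddle heat maps;
`plot_distance_decay()` and `plot_insulation()` draw the tracks.

`run_pipeline("run.yaml")` chains simulate → balance → loopscore →
diffloops → insulation → compartments from a single YAML configuration
and writes a deterministic JSON manifest with per-output checksums.

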