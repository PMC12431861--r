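test_that("summit-window signal summaries are exact on flat tracks", {
  track <- tibble::tibble(chrom = "chrS", start = 0L, end = 10000L,
                          value = 2)
  peaks <- tibble::tibble(chrom = "chrS", start = 4800L, end = 5200L,
                          summit = 5000L)
  expect_equal(peak_signal(peaks, track, "auc_200bp")$signal, 400)
  expect_equal(peak_signal(peaks, track, "mean_100bp")$signal, 2)
  # absent chromosome -> missing
  off <- dplyr::mutate(peaks, chrom = "chrX")
  expect_true(is.na(peak_signal(off, track, "auc_200bp")$signal))
})

test_that("signal extraction matches brute-force per-base summation", {
  # triangular pulse in 1-bp steps
  pos <- 0:399
  val <- pmax(0, 100 - abs(pos - 200))
  track <- tibble::tibble(chrom = "chrS", start = pos, end = pos + 1L,
                          value = val)
  peaks <- tibble::tibble(chrom = "chrS", start = 100L, end = 300L,
                          summit = 210L)
  per_base <- function(lo, hi) {
    sel <- pos >= lo & pos < hi
    val[sel]
  }
  expect_equal(peak_signal(peaks, track, "auc_200bp")$signal,
               sum(per_base(110, 310)))
  expect_equal(peak_signal(peaks, track, "mean_100bp")$signal,
               mean(per_base(160, 260)))
})

test_that("the congruent 25% rule follows the worked examples", {
  mk <- function(r1, r2, a1, a2) {
    tibble::tibble(chrom = "chrS", start = 0L, end = 10L, summit = 5L,
                   ref_1 = r1, ref_2 = r2, alt_1 = a1, alt_2 = a2)
  }
  call <- function(pk) {
    congruent_change_peaks(pk, c("ref_1", "ref_2"),
                           c("alt_1", "alt_2"))$class
  }
  expect_equal(call(mk(10, 10, 13, 12.5)), "gain")
  expect_equal(call(mk(10, 10, 13, 11)), "unchanged")
  expect_equal(call(mk(10, 10, 7.5, 7.0)), "loss")
  expect_equal(call(mk(0, 0, 1, 2)), "gain")   # zero reference, signal gained
  expect_equal(call(mk(0, 0, 0, 0)), "unchanged")
  expect_equal(call(mk(10, 10, 12.5, 12.5)), "gain")  # boundary: exactly 25%
  expect_error(congruent_change_peaks(mk(1, 1, 1, 1), "ref_1",
                                      c("alt_1", "alt_2")),
               "unequal replicate")
})

test_that("noisy twofold changes keep high sensitivity", {
  sim <- simulate_peaks_and_genome(n_peaks = 300, genome_length = 3e5,
                                   noise_sd = 0.1, seed = 91)
  calls <- congruent_change_peaks(sim$peaks, c("ref_1", "ref_2"),
                                  c("alt_1", "alt_2"))
  gains <- sim$peaks$class == "gain"
  losses <- sim$peaks$class == "loss"
  expect_gte(mean(calls$class[gains] == "gain"), 0.9)
  expect_gte(mean(calls$class[losses] == "loss"), 0.9)
})

test_that("CG dinucleotide counting is exact", {
  expect_equal(count_cpg(c("CGCG", "GCGC", "AAAA")), c(2L, 1L, 0L))
  expect_equal(count_cpg("cgcg"), 2L)
  expect_equal(count_cpg(character(0)), integer(0))
})

test_that("promoter windows and overlap annotation follow the flanks", {
  tss <- tibble::tibble(chrom = "chrS", pos = 1000L)
  prom <- define_promoters(tss, flank_bp = 500)
  expect_equal(prom$start, 500L)
  expect_equal(prom$end, 1500L)
  expect_equal(nrow(define_promoters(tss[0, ])), 0L)

  pk <- tibble::tibble(chrom = "chrS", start = 3900L, end = 4100L)
  expect_true(annotate_peak_promoter(pk, tss, flank_bp = 3000)$promoter)
  expect_false(annotate_peak_promoter(pk, tss, flank_bp = 2000)$promoter)
})

test_that("enhancers are acetylated open peaks outside promoters", {
  open <- tibble::tibble(chrom = "chrS",
                         start = c(100L, 500L, 900L),
                         end = c(200L, 600L, 1000L))
  acetyl <- tibble::tibble(chrom = "chrS", start = c(150L, 950L),
                           end = c(250L, 1050L))
  prom <- tibble::tibble(chrom = "chrS", start = 920L, end = 1100L)
  enh <- define_enhancers(open, acetyl, prom)
  expect_equal(enh$start, 100L)  # open+acetyl, outside promoters
  # order independence and idempotence
  enh2 <- define_enhancers(open[3:1, ], acetyl[2:1, ], prom)
  expect_setequal(enh2$start, enh$start)
  expect_equal(define_enhancers(enh, acetyl, prom), enh)
})

test_that("smallest containing domain prefers the tightest span", {
  loops <- tibble::tibble(
    chrom = "chrS",
    start5 = c(100000L, 500000L, 540000L),
    end5 = c(110000L, 510000L, 550000L),
    start3 = c(1100000L, 700000L, 740000L),
    end3 = c(1110000L, 710000L, 750000L),
    bin_i = c(10L, 50L, 54L), bin_j = c(110L, 70L, 74L)
  )
  pt <- tibble::tibble(chrom = "chrS", pos = 600000L)
  d <- smallest_containing_domain(pt, loops)
  expect_equal(d$domain_start, 505000)
  expect_equal(d$domain_span, 200000)

  outside <- smallest_containing_domain(
    tibble::tibble(chrom = "chrS", pos = 5000000L), loops)
  expect_true(is.na(outside$domain_start))

  # exact tie in span -> leftmost 5' midpoint
  tie <- loops[2:3, ]
  d2 <- smallest_containing_domain(
    tibble::tibble(chrom = "chrS", pos = 620000L), tie)
  expect_equal(d2$domain_start, 505000)
})

test_that("flank enhancer counts cover both flanks and skip the body", {
  dom <- tibble::tibble(chrom = "chrS", domain_start = 2000000,
                        domain_end = 3000000)
  enh <- tibble::tibble(
    chrom = "chrS",
    start = c(1600000L, 1700000L, 1900000L,   # 3 in the left flank
              3100000L, 3400000L,             # 2 in the right flank
              2500000L),                      # inside the body
    end = c(1601000L, 1701000L, 1901000L, 3101000L, 3401000L, 2501000L)
  )
  expect_equal(count_flank_enhancers(dom, enh)$n_flank_enhancers, 5L)
  expect_equal(count_flank_enhancers(dom, enh[6, ])$n_flank_enhancers, 0L)
  expect_equal(count_flank_enhancers(dom, enh[0, ])$n_flank_enhancers, 0L)
})

test_that("nearest distances match a brute-force all-pairs minimum", {
  q <- tibble::tibble(chrom = "chrS", start = 995L, end = 1005L)
  s <- tibble::tibble(chrom = "chrS", start = c(2995L, 9995L),
                      end = c(3005L, 10005L))
  expect_equal(nearest_distance(q, s)$nearest_dist, 2000)
  # self-exclusion: a set against itself never reports zero
  self_d <- nearest_distance(s, s)$nearest_dist
  expect_true(all(self_d > 0))

  set.seed(23)
  qs <- tibble::tibble(chrom = sample(c("c1", "c2"), 100, TRUE),
                       start = sample(0:1e6, 100))
  qs$end <- qs$start + 100L
  got <- nearest_distance(qs, qs)$nearest_dist
  mid <- (qs$start + qs$end) %/% 2
  want <- vapply(1:100, function(i) {
    keep <- qs$chrom == qs$chrom[i] & seq_len(100) != i &
      !(qs$start == qs$start[i] & qs$end == qs$end[i])
    if (!any(keep)) return(NA_real_)
    min(abs(mid[keep] - mid[i]))
  }, numeric(1))
  expect_equal(got, want)
})

test_that("set overlap arithmetic follows inclusion-exclusion", {
  ov <- set_overlap_stats(30, 25, 45)
  expect_equal(ov$shared_count, 10L)
  expect_equal(ov$shared_percent, 100 * 10 / 45)
  expect_error(set_overlap_stats(10, 10, 30), "inconsistent")
})
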