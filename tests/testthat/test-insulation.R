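test_that("insulation score is zero on a featureless constant matrix", {
  tr <- insulation_track(const_bm(40))
  defined <- !is.na(tr$score)
  expect_true(any(defined))
  expect_true(all(abs(tr$score[defined]) < 1e-8))
  # undefined within d + floor(s/2) bins of the ends
  expect_true(all(is.na(tr$score[1:6])))
  expect_true(all(is.na(tr$score[35:40])))
})

test_that("a contact-depleted block junction maximizes the score there", {
  m <- matrix(0.1, 100, 100)
  m[1:50, 1:50] <- 1
  m[51:100, 51:100] <- 1
  tr <- insulation_track(as_balanced(m))
  # the maximal score forms a tie plateau symmetric about the junction
  top <- tr$bin[!is.na(tr$score) & tr$score == max(tr$score, na.rm = TRUE)]
  expect_lte(abs(mean(top) - 50), 2)
  pk <- insulation_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start_bin <= 50 && pk$end_bin >= 50)
})

test_that("peak calling applies the threshold, run length and gaps", {
  mk_track <- function(score) {
    structure(tibble::tibble(chrom = "chrS", bin = seq_along(score) - 1L,
                             start = (seq_along(score) - 1L) * 10000L,
                             end = seq_along(score) * 10000L, score = score),
              class = c("insulation_track", class(tibble::tibble())),
              resolution = 10000L)
  }
  sc <- c(0, 0, 0.8, 0.8, 0.8, 0, 0)
  expect_equal(nrow(insulation_peaks(mk_track(sc))), 1L)
  expect_equal(insulation_peaks(mk_track(sc))$start_bin, 2L)
  expect_equal(insulation_peaks(mk_track(sc))$n_bins, 3L)

  expect_equal(nrow(insulation_peaks(mk_track(c(0, 0.8, 0.8, 0)))), 0L)
  expect_equal(nrow(insulation_peaks(mk_track(rep(0.75, 5)))), 0L)
  # missing bins break runs
  sc2 <- c(0.9, 0.9, NA, 0.9, 0.9, 0.9, 0)
  pk <- insulation_peaks(mk_track(sc2))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start_bin, 3L)
  # summit = max score, leftmost on ties
  sc3 <- c(0, 0.8, 1.2, 1.2, 0.9, 0)
  expect_equal(insulation_peaks(mk_track(sc3))$summit_bin, 2L)
})

test_that("per-peak insulation differences average ref minus alt", {
  mk <- function(score) {
    tibble::tibble(chrom = "chrS", bin = seq_along(score) - 1L,
                   start = 0L, end = 0L, score = score)
  }
  ref <- mk(c(1.0, 0.9, 0.8, 0.2))
  pk <- tibble::tibble(chrom = "chrS", start_bin = 0L, end_bin = 2L)

  expect_equal(insulation_delta(pk, ref, ref)$delta_is, 0)
  alt <- mk(c(1.0, 0.9, 0.8, 0.2) - 0.2)
  expect_equal(insulation_delta(pk, ref, alt)$delta_is, 0.2)
  alt2 <- mk(c(0.6, 0.6, 0.6, 0.6))
  expect_equal(insulation_delta(pk, ref, alt2)$delta_is, 0.3)
  # bins missing in either track are excluded; all-missing peaks get NA
  alt3 <- mk(c(NA, 0.6, 0.6, 0.6))
  expect_equal(insulation_delta(pk, ref, alt3)$delta_is, 0.25)
  alt4 <- mk(c(NA, NA, NA, 0.6))
  expect_true(is.na(insulation_delta(pk, ref, alt4)$delta_is))
  expect_error(insulation_delta(pk, ref, mk(c(1, 2))), "binning")
})

sim_boundary_bm <- function(bins, gamma, seed, n_bins = 400) {
  p <- sim_params(n_bins = n_bins, depth = 2e6, seed = seed,
                  boundaries = tibble::tibble(bin = bins,
                                              attenuation = gamma))
  ipf_balance(simulate_contact_map(p)$matrix)
}

test_that("planted boundaries are recovered and featureless maps are clean", {
  planted <- c(80L, 160L, 240L, 320L)
  bm <- sim_boundary_bm(planted, 0.2, seed = 42)
  pk <- insulation_peaks(insulation_track(bm))
  mid <- (pk$start_bin + pk$end_bin) / 2
  hit <- vapply(planted, function(b) any(abs(mid - b) <= 2), logical(1))
  expect_gte(mean(hit), 0.9)

  flat <- ipf_balance(simulate_contact_map(
    sim_params(n_bins = 400, depth = 2e6, seed = 43))$matrix)
  expect_equal(nrow(insulation_peaks(insulation_track(flat))), 0L)
})

test_that("boundary weakening shrinks the insulation difference", {
  ref <- sim_boundary_bm(200L, 0.2, seed = 50)
  tr_ref <- insulation_track(ref)
  pk <- insulation_peaks(tr_ref)
  expect_gte(nrow(pk), 1L)
  deltas <- vapply(c(0.3, 0.6, 0.95), function(g) {
    alt <- sim_boundary_bm(200L, g, seed = 51)
    mean(insulation_delta(pk, tr_ref, insulation_track(alt))$delta_is)
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("shifting the planted boundary shifts the called peak equally", {
  base <- sim_boundary_bm(180L, 0.2, seed = 60)
  pk0 <- insulation_peaks(insulation_track(base))
  shifted <- sim_boundary_bm(205L, 0.2, seed = 60)
  pk1 <- insulation_peaks(insulation_track(shifted))
  expect_equal(nrow(pk0), 1L)
  expect_equal(nrow(pk1), 1L)
  mid0 <- (pk0$start_bin + pk0$end_bin) / 2
  mid1 <- (pk1$start_bin + pk1$end_bin) / 2
  expect_lte(abs((mid1 - mid0) - 25), 2)
})
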