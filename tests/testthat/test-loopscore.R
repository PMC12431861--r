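one_loop <- function(bi, bj) {
  tibble::tibble(chrom = "chrS", start5 = bi * 10000L,
                 end5 = (bi + 1L) * 10000L, start3 = bj * 10000L,
                 end3 = (bj + 1L) * 10000L,
                 bin_i = as.integer(bi), bin_j = as.integer(bj))
}

test_that("loop signal window arithmetic is exact", {
  bm <- const_bm(60, c = 3)
  q <- loop_signal(one_loop(20, 40), bm)
  expect_equal(q$signal_mean, 3)
  expect_equal(q$strength_sum, 75)

  m <- matrix(0, 60, 60)
  m[21, 41] <- 5
  m[41, 21] <- 5
  bm0 <- as_balanced(m)
  q <- loop_signal(one_loop(20, 40), bm0)
  expect_equal(q$signal_mean, 0.2)
  expect_equal(q$strength_sum, 5)

  edge <- loop_signal(one_loop(1, 40), const_bm(60))
  expect_false(edge$scoreable)
})

test_that("donut candidate ring matches the combinatorial oracle", {
  ring <- donut_ring_offsets(8)
  grid <- expand.grid(dx = -8:8, dy = -8:8)
  oracle <- grid[pmax(abs(grid$dx), abs(grid$dy)) == 8, ]
  expect_equal(nrow(ring), 64L)
  expect_equal(nrow(ring), nrow(oracle))
  expect_setequal(paste(ring$dx, ring$dy), paste(oracle$dx, oracle$dy))
})

test_that("usable donut squares equal a brute-force filter at random loops", {
  set.seed(19)
  n <- 120L
  oracle_offsets <- function(ci, cj) {
    keep <- list()
    for (dx in -8:8) for (dy in -8:8) {
      if (max(abs(dx), abs(dy)) != 8) next
      rows <- (ci + dx - 2):(ci + dx + 2)
      cols <- (cj + dy - 2):(cj + dy + 2)
      if (min(rows) < 0 || min(cols) < 0 || max(rows) >= n ||
          max(cols) >= n) next
      if (max(rows) >= min(cols)) next  # any cell with row >= col
      keep[[length(keep) + 1L]] <- c(dx, dy)
    }
    if (!length(keep)) return(character(0))
    sort(vapply(keep, paste, character(1), collapse = ","))
  }
  for (rep in 1:50) {
    ci <- sample(0:(n - 1), 1)
    cj <- sample(0:(n - 1), 1)
    got <- loopscape:::usable_donut_offsets(n, ci, cj, 8L, 2L)
    expect_identical(sort(paste(got$dx, got$dy, sep = ",")),
                     oracle_offsets(ci, cj))
  }
})

test_that("donut background is exact on constants and seed-stable", {
  bm <- const_bm(80, c = 1.7)
  for (seed in c(1, 99)) {
    q <- donut_background(one_loop(30, 60), bm, seed = seed)
    expect_equal(q$background, 1.7)
    expect_equal(q$n_background, 15L)
  }
  set.seed(123)  # ambient RNG state must not leak in
  p <- sim_params(n_bins = 80, depth = 5e5, seed = 3)
  bm2 <- ipf_balance(simulate_contact_map(p)$matrix)
  a <- donut_background(one_loop(30, 60), bm2, seed = 7)
  b <- donut_background(one_loop(30, 60), bm2, seed = 7)
  expect_identical(a$background, b$background)
})

test_that("loop score calibrates to log2 enrichment", {
  expect_equal(score_loops(one_loop(30, 60), const_bm(80), seed = 1)$ls, 0,
               tolerance = 1e-8)

  # centroid window exactly 2x the background level
  scores <- vapply(1:50, function(seed) {
    m <- matrix(1, 100, 100)
    m[29:33, 59:63] <- 2
    m[59:63, 29:33] <- 2
    score_loops(one_loop(30, 60), as_balanced(m), seed = seed)$ls
  }, numeric(1))
  expect_lt(max(abs(scores - 1)), 0.05)
})

test_that("LS is centered on featureless decay and increases with amplitude", {
  p <- sim_params(n_bins = 400, depth = 4e6, seed = 12)
  bm <- ipf_balance(simulate_contact_map(p)$matrix)
  # random off-diagonal positions scored as if they were loops
  set.seed(14)
  off <- sample(15:60, 100, replace = TRUE)
  bi <- vapply(off, function(o) sample(20:(400 - 21 - o), 1), integer(1))
  pos <- tibble::tibble(bin_i = as.integer(bi), bin_j = as.integer(bi + off))
  loops <- tibble::tibble(chrom = "chrS",
                          start5 = pos$bin_i * 10000L,
                          end5 = (pos$bin_i + 1L) * 10000L,
                          start3 = pos$bin_j * 10000L,
                          end3 = (pos$bin_j + 1L) * 10000L,
                          bin_i = pos$bin_i, bin_j = pos$bin_j)
  q <- score_loops(loops, bm, seed = 5)
  expect_lt(abs(median(q$ls, na.rm = TRUE)), 0.15)

  # fixed background, growing planted amplitude
  ls_at <- vapply(c(1, 2, 4, 8), function(lam) {
    m <- matrix(1, 100, 100)
    m[29:33, 59:63] <- lam
    m[59:63, 29:33] <- lam
    score_loops(one_loop(30, 60), as_balanced(m), seed = 3)$ls
  }, numeric(1))
  expect_true(all(diff(ls_at) > 0))
})

test_that("architectural classification needs LS > 1 and convergent motifs", {
  base <- one_loop(30, 60)
  mk <- function(ls, f5, r3) {
    dplyr::mutate(base, ls = ls, forward5 = f5, reverse3 = r3)
  }
  expect_equal(nrow(classify_architectural(mk(1.2, TRUE, TRUE))), 1L)
  expect_equal(nrow(classify_architectural(mk(2, TRUE, FALSE))), 0L)
  expect_equal(nrow(classify_architectural(mk(0.8, TRUE, TRUE))), 0L)
  expect_equal(nrow(classify_architectural(mk(1.0, TRUE, TRUE))), 0L)
})

test_that("anchor motif annotation distinguishes convergent from tandem", {
  loops <- one_loop(10, 50)
  conv <- tibble::tibble(chrom = "chrS",
                         start = c(102000L, 503000L),
                         end = c(102400L, 503400L),
                         strand = c("+", "-"))
  tand <- dplyr::mutate(conv, strand = c("+", "+"))
  a <- annotate_loop_anchors(loops, conv)
  expect_true(a$forward5 && a$reverse3)
  b <- annotate_loop_anchors(loops, tand)
  expect_true(b$forward5)
  expect_false(b$reverse3)
})

test_that("APA averages windows and applies the distance filter", {
  bm <- const_bm(120, c = 2)
  res <- apa(one_loop(40, 80), bm)
  expect_true(all(res$mean_matrix == 2))
  expect_equal(res$apa_score, 1)

  # 90 kb separation is excluded at the >100 kb filter
  expect_error(apa(one_loop(40, 49), bm), "no eligible loops")
  res2 <- apa(dplyr::bind_rows(one_loop(40, 49), one_loop(40, 80)), bm)
  expect_equal(res2$n_loops_used, 1L)

  pos <- plant_loops(20, 400, min_offset = 30, seed = 6)
  p <- sim_params(n_bins = 400, depth = 4e6, seed = 7,
                  loops = tibble::tibble(bin_i = pos$bin_i,
                                         bin_j = pos$bin_j,
                                         amplitude = 4, spread = 1))
  sim <- simulate_contact_map(p)
  bm2 <- ipf_balance(sim$matrix)
  res3 <- apa(sim$truth$loops, bm2)
  w <- 2 * res3$window_halfwidth + 1
  expect_equal(which.max(res3$mean_matrix),
               (res3$window_halfwidth) * w + res3$window_halfwidth + 1)
  expect_gt(res3$apa_score, 1)
})

test_that("condition-specific calls require full pairwise consistency", {
  mk_quants <- function(strengths, lss) {
    purrr::imap_dfr(strengths, function(s, id) {
      tibble::tibble(sample = id, bin_i = 10L, bin_j = 40L,
                     strength_sum = s, ls = lss[[id]])
    })
  }
  q <- mk_quants(list(w1 = 10, w2 = 9, m1 = 8, m2 = 7),
                 list(w1 = 1.5, w2 = 1.4, m1 = 1.0, m2 = 0.9))
  expect_equal(condition_specific_loops(q, c("w1", "w2"),
                                        c("m1", "m2"))$call, "weakened")

  q2 <- mk_quants(list(w1 = 10, w2 = 6, m1 = 8, m2 = 7),
                  list(w1 = 1.5, w2 = 1.4, m1 = 1.0, m2 = 0.9))
  expect_equal(condition_specific_loops(q2, c("w1", "w2"),
                                        c("m1", "m2"))$call, "unchanged")

  q3 <- mk_quants(list(w1 = 5, w2 = 5, m1 = 5, m2 = 5),
                  list(w1 = 1, w2 = 1, m1 = 1, m2 = 1))
  expect_equal(condition_specific_loops(q3, c("w1", "w2"),
                                        c("m1", "m2"))$call, "unchanged")

  expect_error(condition_specific_loops(q, character(0), c("m1", "m2")),
               "non-empty")
})
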