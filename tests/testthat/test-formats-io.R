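test_that("triplet contact reading mirrors, sums duplicates, validates", {
  f <- withr::local_tempfile()
  writeLines(c("0\t0\t4", "0\t2\t1"), f)
  cm <- read_contact_matrix(f, n_bins = 3)
  expect_equal(cm$values[1, 1], 4)
  expect_equal(cm$values[1, 3], 1)
  expect_equal(cm$values[3, 1], 1)
  expect_equal(sum(cm$values), 6)

  writeLines(c("1\t2\t3", "2\t1\t2"), f)
  cm <- read_contact_matrix(f, n_bins = 4)
  expect_equal(cm$values[2, 3], 5)
  expect_equal(cm$values[3, 2], 5)

  writeLines("0\t1\t-3", f)
  expect_error(read_contact_matrix(f, n_bins = 2), "negative count at line 1")
  writeLines(c("0\t0\t1", "0\t5\t2"), f)
  expect_error(read_contact_matrix(f, n_bins = 3), "line 2")
})

test_that("contact matrix write/read round-trips a random symmetric matrix", {
  set.seed(7)
  m <- matrix(rpois(2500, 2), 50, 50)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_matrix(m)
  f <- withr::local_tempfile()
  b <- withr::local_tempfile()
  write_contact_matrix(cm, f, bins = b)
  back <- read_contact_matrix(f, bins = b)
  expect_identical(back$values, cm$values)
  expect_equal(back$resolution, cm$resolution)
  expect_equal(back$chrom, cm$chrom)
})

test_that("hicpro dialect shifts 1-based bin ids", {
  f <- withr::local_tempfile()
  writeLines("1\t3\t7", f)
  cm <- read_contact_matrix(f, dialect = "hicpro", n_bins = 3)
  expect_equal(cm$values[1, 3], 7)
})

test_that("BEDPE loops get centroid bins and anchor ordering", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100000\t110000\tchr1\t400000\t410000",
    "chr1\t400000\t410000\tchr1\t100000\t110000",
    "chr1\t100000\t110000\tchr2\t400000\t410000"
  ), f)
  loops <- read_bedpe(f, resolution = 10000)
  expect_equal(nrow(loops), 2L)
  expect_equal(loops$bin_i, c(10L, 10L))
  expect_equal(loops$bin_j, c(40L, 40L))
  expect_true(all(loops$bin_i < loops$bin_j))
  expect_true(all(loops$start5 < loops$start3))
  expect_equal(attr(loops, "n_interchromosomal"), 1L)
})

test_that("BEDPE write/read round-trips many records", {
  set.seed(11)
  n <- 1000
  a <- sort(sample(0:5000, n)) * 1000L
  b <- a + sample(200:400, n, replace = TRUE) * 1000L
  loops <- tibble::tibble(chrom = "chr1", start5 = a, end5 = a + 10000L,
                          start3 = b, end3 = b + 10000L)
  f <- withr::local_tempfile()
  write_bedpe(loops, f)
  back <- read_bedpe(f, resolution = 10000)
  expect_equal(back$start5, loops$start5)
  expect_equal(back$end3, loops$end3)
})

test_that("narrowPeak summits use the offset column, BED the midpoint", {
  f <- withr::local_tempfile()
  writeLines(paste(c("chr1", 1000, 1400, "p1", 0, ".", 5, -1, -1, 150),
                   collapse = "\t"), f)
  pk <- read_bed_peaks(f)
  expect_equal(pk$summit, 1150L)

  writeLines("chr1\t1000\t1401", f)
  pk <- read_bed_peaks(f)
  expect_equal(pk$summit, (1000L + 1401L) %/% 2L)

  writeLines(character(0), f)
  expect_warning(pk <- read_bed_peaks(f), "empty")
  expect_equal(nrow(pk), 0L)
})

test_that("PFM counts become pseudocounted probabilities", {
  f <- withr::local_tempfile()
  writeLines(c(">toy",
               "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  p <- read_pfm(f)
  expect_equal(unname(p$prob["A", 1]), 8.01 / 8.04, tolerance = 1e-12)
  expect_equal(unname(p$prob["C", 1]), 0.01 / 8.04, tolerance = 1e-12)
  expect_equal(colSums(p$prob), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-9)
  f2 <- withr::local_tempfile()
  write_pfm(p, f2)
  back <- read_pfm(f2, pseudocount = 0)
  expect_equal(back$prob, p$prob, tolerance = 1e-9)
})

test_that("FASTA round-trips and maps non-ACGT to N", {
  f <- withr::local_tempfile()
  writeLines(c(">s1 description", "ACGTRYacgt"), f)
  s <- read_fasta(f)
  expect_equal(names(s), "s1")
  expect_equal(unname(s), "ACGTNNACGT")
  f2 <- withr::local_tempfile()
  write_fasta(s, f2)
  expect_equal(unname(read_fasta(f2)), "ACGTNNACGT")
})

test_that("bedGraph round-trips", {
  tr <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                       end = c(100L, 250L), value = c(1.5, 2))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  expect_equal(as.data.frame(read_bedgraph(f)), as.data.frame(tr))
})

test_that("coordinate-convention conversion is an involution", {
  set.seed(3)
  x <- tibble::tibble(chrom = "chr1",
                      start = sample(0:1e6, 200),
                      end = integer(200))
  x$end <- x$start + sample(1:1000, 200, replace = TRUE)
  expect_identical(to_zero_based(to_one_based(x)), x)
})
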