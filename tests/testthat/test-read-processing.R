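clen1 <- chrom_lengths("chr1", 100000L)

test_that("reads extend strand-aware from 51 to 400 nt with clamping", {
  reads <- tibble::tibble(
    chrom = "chr1",
    start = c(1001L, 5000L, 20L),
    end = c(1051L, 5050L, 70L),
    strand = c("+", "-", "-"),
    name = c("f", "r", "rc"))
  ext <- extend_reads(reads, 400, clen1)
  expect_equal(ext$start, c(1001L, 4651L, 1L))
  expect_equal(ext$end, c(1400L, 5050L, 70L))
  expect_equal(ext$end[1] - ext$start[1] + 1L, 400L)
  # counts preserved, no interval longer than target
  expect_equal(nrow(ext), nrow(reads))
  expect_true(all(ext$end - ext$start + 1 <= 400))
  # a read already >= target passes through unchanged
  long <- tibble::tibble(chrom = "chr1", start = 100L, end = 700L,
                         strand = "+", name = "l")
  expect_equal(extend_reads(long, 400, clen1)[, 1:3], long[, 1:3])
  # unknown chromosome is named in the error
  expect_error(
    extend_reads(tibble::tibble(chrom = "chrZ", start = 1L, end = 51L,
                                strand = "+", name = "x"), 400, clen1),
    "chrZ")
})

test_that("window counting increments every window a read overlaps", {
  cl <- chrom_lengths("chr1", 450L)
  iv3 <- genomic_intervals(rep("chr1", 3), c(1, 5, 100), c(50, 60, 150))
  cov <- window_coverage(iv3, cl, 150)
  expect_equal(cov$count, c(3L, 0L, 0L))
  straddle <- genomic_intervals("chr1", 140, 160)
  expect_equal(window_coverage(straddle, cl, 150)$count, c(1L, 1L, 0L))
  empty <- genomic_intervals(character(), integer(), integer())
  expect_equal(window_coverage(empty, cl, 150)$count, c(0L, 0L, 0L))
})

test_that("window counts agree with the per-interval oracle on random data", {
  set.seed(13)
  for (trial in 1:20) {
    clen <- sample(300:900, 1)
    w <- sample(c(50, 150), 1)
    n <- sample(0:30, 1)
    iv <- if (n > 0) {
      genomic_intervals("c1", s <- sample(clen, n, replace = TRUE),
                        pmin(clen, s + sample(0:200, n, replace = TRUE)))
    } else genomic_intervals(character(), integer(), integer())
    got <- window_coverage(iv, chrom_lengths("c1", clen), w)
    expect_equal(got$count, oracle_window_counts(iv, "c1", clen, w))
    # totals identity: sum of counts = total windows overlapped
    expect_equal(sum(got$count),
                 sum(vapply(seq_len(nrow(iv)), function(i) {
                   sum(oracle_window_counts(iv[i, ], "c1", clen, w))
                 }, 0L)))
  }
})

test_that("the Poisson caller is quiet when chip equals input", {
  iv <- genomic_intervals(rep("chr1", 20), seq(1, 2900, by = 150),
                          seq(100, 3000, by = 150))
  cl <- chrom_lengths("chr1", 3000L)
  cov <- window_coverage(iv, cl, 150)
  peaks <- call_enriched_regions(cov, cov, caller_params())
  expect_equal(nrow(peaks), 0)
})

test_that("a strongly enriched window is significant per the Poisson tail", {
  cl <- chrom_lengths("chr1", 600L)
  empty <- genomic_intervals(character(), integer(), integer())
  chip <- window_coverage(empty, cl, 150)
  input <- chip
  chip$count <- c(50L, 0L, 0L, 0L)
  input$count <- c(5L, 0L, 0L, 0L)
  params <- caller_params(p_threshold = 1e-5, min_windows = 1,
                          pseudocount = 1, scale = 1)
  peaks <- call_enriched_regions(chip, input, params)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$start, 1L)
  expect_equal(peaks$end, 150L)
  # the p-value matches an independent Poisson tail-sum oracle
  p_oracle <- oracle_pois_tail(50, 6)
  expect_lt(p_oracle, 1e-5)
  expect_equal(peaks$score, trunc(-10 * log10(p_oracle) * 10) / 10,
               tolerance = 1e-6)
  expect_equal(peaks$summit, 75L)
})

test_that("adjacent significant windows merge into one peak", {
  cl <- chrom_lengths("chr1", 900L)
  empty <- genomic_intervals(character(), integer(), integer())
  chip <- window_coverage(empty, cl, 150)
  input <- chip
  chip$count <- c(0L, 60L, 55L, 0L, 40L, 0L)
  params <- caller_params(p_threshold = 1e-5, min_windows = 2,
                          pseudocount = 1, scale = 1)
  peaks <- call_enriched_regions(chip, input, params)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$start, 151L)
  expect_equal(peaks$end, 450L)
  expect_equal(peaks$n_windows, 2L)
})

test_that("raising a chip count or the threshold never loses a peak", {
  cl <- chrom_lengths("chr1", 1500L)
  empty <- genomic_intervals(character(), integer(), integer())
  base <- window_coverage(empty, cl, 150)
  input <- base
  chip <- base
  chip$count <- c(0L, 30L, 35L, 0L, 0L, 25L, 28L, 0L, 0L, 0L)
  params <- caller_params(p_threshold = 1e-5, min_windows = 2,
                          pseudocount = 1, scale = 1)
  p0 <- call_enriched_regions(chip, input, params)
  chip2 <- chip
  chip2$count[2] <- chip2$count[2] + 50L
  p1 <- call_enriched_regions(chip2, input, params)
  covered <- function(before, after) {
    all(vapply(seq_len(nrow(before)), function(i) {
      any(after$start <= before$start[i] & after$end >= before$end[i])
    }, TRUE))
  }
  expect_true(covered(p0, p1))
  p2 <- call_enriched_regions(
    chip, input, caller_params(p_threshold = 1e-3, min_windows = 2,
                               pseudocount = 1, scale = 1))
  expect_true(covered(p0, p2))
})

test_that("mismatched window grids are rejected", {
  empty <- genomic_intervals(character(), integer(), integer())
  a <- window_coverage(empty, chrom_lengths("chr1", 600L), 150)
  b <- window_coverage(empty, chrom_lengths("chr1", 600L), 100)
  expect_error(call_enriched_regions(a, b), "grid")
})
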