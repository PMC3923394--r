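test_that("segment widths split the zone near-equally, extras first", {
  w <- chipscape:::segment_widths(1000L, 100L)
  expect_true(all(w == 10L))
  w2 <- chipscape:::segment_widths(1037L, 100L)
  expect_equal(sum(w2), 1037L)
  expect_equal(w2[1:37], rep(11L, 37))
  expect_equal(w2[38:100], rep(10L, 63))
})

test_that("gene profiles count a read in every segment it overlaps", {
  full <- genomic_intervals("chr1", 1, 1000)
  p <- gene_profile(full, "chr1", 1, 1000, "+")
  expect_equal(p, rep(1L, 100))
  # a read in the first decile touches only the first 10 segments
  head_read <- genomic_intervals("chr1", 1, 100)
  p2 <- gene_profile(head_read, "chr1", 1, 1000, "+")
  expect_equal(which(p2 > 0), 1:10)
  # reverse-strand genes report 5'->3': genomic left end lands in segment 100
  left_base <- genomic_intervals("chr1", 1, 5)
  p3 <- gene_profile(left_base, "chr1", 1, 1000, "-")
  expect_equal(which(p3 > 0), 100L)
})

test_that("profiles of short zones use zero-width segments safely", {
  iv <- genomic_intervals("chr1", 10, 40)
  p <- gene_profile(iv, "chr1", 1, 60, "+")  # zone shorter than 100 bp
  expect_equal(length(p), 100)
  expect_equal(sum(p > 0), 31)  # one segment per covered base
})

test_that("normalization rescales to the gene maximum and skips silence", {
  expect_equal(normalize_gene_profile(c(10, 40, 20)), c(0.25, 1, 0.5))
  expect_equal(normalize_gene_profile(rep(7, 5)), rep(1, 5))
  expect_warning(out <- normalize_gene_profile(rep(0, 5)), "skipped")
  expect_null(out)
})

test_that("averaging is the segment-wise mean with equal gene weight", {
  prof <- average_profiles(list(c(1, 0, 0.5), c(0.5, 1, 0.5)))
  expect_equal(prof$value, c(0.75, 0.5, 0.5))
  single <- average_profiles(list(c(0.2, 1)))
  expect_equal(single$value, c(0.2, 1))
  expect_error(average_profiles(list()), "no profiles")
  expect_equal(attr(prof, "n_genes"), 2)
})

test_that("per-gene depth scaling does not change the metagene", {
  set.seed(3)
  reads <- genomic_intervals("chr1", s <- sample(900, 50, replace = TRUE),
                             s + 49)
  p1 <- normalize_gene_profile(gene_profile(reads, "chr1", 1, 1000, "+"))
  doubled <- dplyr::bind_rows(reads, reads)
  p2 <- normalize_gene_profile(gene_profile(doubled, "chr1", 1, 1000, "+"))
  expect_equal(p1, p2)
})

test_that("mirroring genome and strand reverses a profile exactly", {
  set.seed(5)
  L <- 5000L
  reads <- genomic_intervals("chr1", s <- sample(L - 100, 80, replace = TRUE),
                             s + sample(20:100, 80, replace = TRUE))
  zs <- 501L; ze <- 3500L
  fwd <- gene_profile(reads, "chr1", zs, ze, "+")
  mirrored <- genomic_intervals("chr1", L - reads$end + 1L, L - reads$start + 1L)
  rev <- gene_profile(mirrored, "chr1", L - ze + 1L, L - zs + 1L, "-")
  expect_equal(rev, fwd)
})

test_that("gene selection follows the majority-coverage rule", {
  genes <- generate_gene_models(60000, 3, seed = 7)
  cl <- chrom_lengths("chr1", 60000)
  regions <- genic_regions(genes, cl)
  prom1 <- regions[regions$zone == "promoter" &
                     regions$gene_id == genes$gene_id[1], ]
  body2 <- regions[regions$zone == "gene_body" &
                     regions$gene_id == genes$gene_id[2], ]
  reads <- dplyr::bind_rows(
    genomic_intervals("chr1", prom1$start + 10, prom1$start + 400),
    genomic_intervals("chr1", body2$start + 10, body2$start + 400))
  totals <- zone_coverage_totals(reads, regions)
  expect_equal(select_genes_for_zone(totals, "promoter"), genes$gene_id[1])
  expect_equal(select_genes_for_zone(totals, "gene_body"), genes$gene_id[2])
  # an uncovered gene qualifies for no zone
  expect_false(genes$gene_id[3] %in% unlist(
    lapply(c("promoter", "gene_body", "downstream"),
           function(z) select_genes_for_zone(totals, z))))
})

test_that("centre-planted gene-body sites give a centred unimodal profile", {
  sim <- simulate_chip_experiment(
    plan = c(gene_body = 8L), placement = "center",
    config = simulation_config(enrichment = 80, background_depth = 0.005),
    seed = 101)
  ext <- extend_reads(sim$chip_reads, 400, sim$chrom_lengths)
  regions <- genic_regions(sim$genes, sim$chrom_lengths)
  prof <- metagene_profile(ext, regions, "gene_body")
  expect_gte(which.max(prof$value), 40)
  expect_lte(which.max(prof$value), 60)
  # edges are depressed relative to the centre
  expect_gt(mean(prof$value[45:55]), mean(c(prof$value[1:5], prof$value[96:100])))
})

test_that("uniformly planted promoter sites give a flat promoter profile", {
  sim <- simulate_chip_experiment(
    plan = c(promoter = 12L), placement = "uniform",
    config = simulation_config(enrichment = 80, background_depth = 0.005),
    seed = 103)
  # the planted positions themselves are uniform within their promoters
  regions <- genic_regions(sim$genes, sim$chrom_lengths)
  prom <- regions[regions$zone == "promoter", ]
  rel <- vapply(seq_len(nrow(sim$sites)), function(i) {
    z <- prom[prom$gene_id == sim$sites$gene_id[i], ]
    (sim$sites$start[i] - z$start) / (z$end - z$start - 6)
  }, 0)
  ks <- stats::ks.test(rel, "punif")
  expect_gt(ks$p.value, 0.01)
  # and the averaged profile shows no dominant mode
  ext <- extend_reads(sim$chip_reads, 400, sim$chrom_lengths)
  prof <- metagene_profile(ext, regions, "promoter")
  p <- prof$value / sum(prof$value)
  d <- max(abs(cumsum(p) - seq_len(100) / 100))
  expect_lt(d, 1.63 / sqrt(nrow(sim$sites)))  # KS bound at alpha = 0.01
})
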