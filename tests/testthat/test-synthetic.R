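test_that("composition model rejects degenerate GC fractions", {
  expect_error(composition_model(0), "between 0 and 1")
  expect_error(composition_model(1), "between 0 and 1")
  cm <- composition_model(0.332)
  expect_equal(sum(as.numeric(cm)), 1)
  expect_equal(unname(cm["G"]), unname(cm["C"]))
  expect_equal(unname(cm["A"]), unname(cm["T"]))
})

test_that("generated genomes are seed-deterministic with the requested GC", {
  g1 <- generate_genome(200000, composition_model(0.332), seed = 5)
  g2 <- generate_genome(200000, composition_model(0.332), seed = 5)
  expect_identical(g1, g2)
  gc <- gc_fraction(g1)
  sd3 <- 3 * sqrt(0.332 * 0.668 / 200000)
  expect_lt(abs(gc - 0.332), sd3)
})

test_that("gene packing is feasibility-checked and genic regions disjoint", {
  expect_error(generate_gene_models(1000, 50, seed = 1), "cannot pack")
  genes <- generate_gene_models(100000, 5, seed = 9)
  expect_true(all(c("+", "-") %in% genes$strand) || nrow(genes) < 4)
  regions <- genic_regions(genes, chrom_lengths("chr1", 100000))
  spans <- regions |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop") |>
    dplyr::arrange(start)
  if (nrow(spans) > 1) {
    expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
  }
  # every exon inside its gene, first/last exon flush with gene ends
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_equal(ex$start[1], genes$start[i])
    expect_equal(ex$end[nrow(ex)], genes$end[i])
  }
})

test_that("planted sites match the pattern on their strand and zone", {
  genes <- generate_gene_models(100000, 8, seed = 21)
  genome <- generate_genome(100000, composition_model(0.332), seed = 22)
  planted <- plant_sites(genome, genes,
                         c(promoter = 3, gene_body = 2, intergenic = 1),
                         seed = 23)
  sites <- planted$sites
  expect_equal(nrow(sites), 6)
  words <- oracle_expand("WRGCCCA")
  for (i in seq_len(nrow(sites))) {
    found <- substring(planted$genome[[1]], sites$start[i], sites$end[i])
    on_strand <- if (sites$strand[i] == "+") found else oracle_revcomp(found)
    expect_true(on_strand %in% words)
    # scanning the planted locus finds at least one hit
    hits <- hit_positions(found, "WRGCCCA", "both")
    expect_gte(nrow(hits), 1)
  }
  # zone labels are re-derivable by single-anchor classification
  ann <- classify_peaks(sites[, c("chrom", "start", "end")],
                        genic_regions(genes, chrom_lengths("chr1", 100000)))
  expect_equal(ann$zone, sites$zone)
})

test_that("reverse-strand planting writes the reverse complement forward", {
  genes <- generate_gene_models(60000, 3, seed = 31)
  genome <- generate_genome(60000, composition_model(0.332), seed = 32)
  # find a seed giving at least one reverse-strand site
  planted <- plant_sites(genome, genes, c(gene_body = 3), seed = 33)
  rev_sites <- planted$sites[planted$sites$strand == "-", ]
  for (i in seq_len(nrow(rev_sites))) {
    fwd_seq <- substring(planted$genome[[1]], rev_sites$start[i],
                         rev_sites$end[i])
    expect_equal(fwd_seq, oracle_revcomp(rev_sites$sequence[i]))
  }
  # e.g. AAGCCCA planted on minus shows TGGGCTT
  expect_equal(oracle_revcomp("AAGCCCA"), "TGGGCTT")
})

test_that("simulated fragments scatter around site centres and split strands", {
  genome <- generate_genome(50000, seed = 41)
  site <- tibble::tibble(chrom = "chr1", start = 25000L, end = 25006L,
                         zone = "intergenic", gene_id = NA, strand = "+",
                         sequence = "AAGCCCA")
  cfg <- simulation_config(enrichment = 1000, background_depth = 0, seed = 42)
  reads <- simulate_chip_reads(genome, site, cfg)
  n <- nrow(reads)
  expect_gt(n, 800)
  # recover fragment midpoints from read geometry
  mids <- ifelse(reads$strand == "+", reads$start + 200, reads$end - 200)
  center <- 25003
  expect_lt(abs(mean(mids) - center), 3 * 100 / sqrt(n) + 1)
  p_fwd <- mean(reads$strand == "+")
  expect_lt(abs(p_fwd - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(reads$start >= 1 & reads$end <= 50000))
})

test_that("empty simulations and determinism contracts hold", {
  genome <- generate_genome(10000, seed = 51)
  empty_sites <- plant_sites(genome, generate_gene_models(10000, 1, seed = 52),
                             c(promoter = 0), seed = 53)$sites
  cfg0 <- simulation_config(enrichment = 0, background_depth = 0, seed = 54)
  expect_equal(nrow(simulate_chip_reads(genome, empty_sites, cfg0)), 0)
  cfg <- simulation_config(background_depth = 0.02, seed = 55)
  r1 <- simulate_input_reads(genome, cfg)
  r2 <- simulate_input_reads(genome, cfg)
  expect_identical(r1, r2)
})

test_that("input read counts follow the Poisson depth", {
  genome <- generate_genome(100000, seed = 61)
  depth <- 0.02
  cfg <- simulation_config(background_depth = depth, seed = 62)
  reads <- simulate_input_reads(genome, cfg)
  lambda <- depth * 100000
  expect_lt(abs(nrow(reads) - lambda), 3 * sqrt(lambda))
  expect_true(all(reads$start >= 1 & reads$end <= 100000))
})

test_that("an unplanted genome carries the motif at its null frequency", {
  genome <- generate_genome(300000, composition_model(0.332), seed = 71)
  counts <- count_hits(genome[[1]], "WRGCCCA", "both")
  p <- expected_frequency("WRGCCCA", composition_model(0.332), "both")
  expected <- p * counts$total_bp
  expect_lt(abs(counts$n_hits - expected), 3 * sqrt(expected))
})
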