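#' Pipeline run configuration
#'
#' Bundles every stage parameter of an end-to-end run with its default:
#' 150 bp coverage windows, extension of reads to 400 bp fragments, a
#' genic region of 3 kb upstream to 1 kb downstream, 100 metagene
#' segments, the `WRGCCCA` consensus and a GC null measured from the
#' genome (`gc = "auto"`). Input is either a simulation request (the
#' default) or paths to a FASTA genome, GFF3 genes and BED read files.
#'
#' @param simulate Run on simulated data (default `TRUE`).
#' @param genome_path,genes_path,chip_path,input_path File inputs used
#'   when `simulate = FALSE`.
#' @param genome_length,n_genes,plan,placement,sim_config Simulation
#'   parameters, passed to [simulate_chip_experiment()].
#' @param window Coverage window size in bp.
#' @param extend Fragment length reads are extended to.
#' @param upstream,downstream Genic-region extents in bp.
#' @param n_segments Metagene segments.
#' @param pattern Consensus IUPAC pattern.
#' @param gc `"auto"` (measure from the genome) or a numeric GC fraction
#'   for the motif null.
#' @param strands Motif scanning mode, `"both"` or `"forward"`.
#' @param caller A [caller_params()].
#' @param categories Optional gene-to-category tibble for the
#'   over-representation stage.
#' @param genome_size_genes Annotated-genome size `N` for enrichment;
#'   defaults to the number of genes in the annotation.
#' @param seed Root seed; stage seeds derive from it by fixed offsets.
#' @param outdir Optional directory; when set, every stage output plus a
#'   checksummed manifest is written there.
#' @return An object of class `chipscape_config`.
#' @export
chipscape_config <- function(simulate = TRUE,
                             genome_path = NULL, genes_path = NULL,
                             chip_path = NULL, input_path = NULL,
                             genome_length = 150000L, n_genes = 20L,
                             plan = c(promoter = 5L, gene_body = 5L),
                             placement = "center",
                             sim_config = simulation_config(),
                             window = 150L, extend = 400L,
                             upstream = 3000L, downstream = 1000L,
                             n_segments = 100L, pattern = "WRGCCCA",
                             gc = "auto", strands = "both",
                             caller = caller_params(),
                             categories = NULL, genome_size_genes = NULL,
                             seed = 1L, outdir = NULL) {
  if (!simulate &&
      (is.null(genome_path) || is.null(genes_path) ||
       is.null(chip_path) || is.null(input_path))) {
    abort("non-simulated runs need genome, genes, chip and input paths")
  }
  structure(as.list(environment()), class = "chipscape_config")
}

#' Run the full ChIP-seq downstream pipeline
#'
#' Orchestrates simulate (or load) -> extend -> window coverage -> call
#' enriched regions -> genic-zone annotation -> metagene profiles ->
#' consensus-motif statistics -> category over-representation, single
#' threaded and fully deterministic under the configured seed. When
#' `config$outdir` is set, each stage's table is written (BED/GFF3/FASTA/
#' TSV) along with a JSON manifest carrying the seed, record counts and
#' MD5 checksums of every emitted file.
#'
#' @param config A [chipscape_config()].
#' @return An object of class `chipscape_run`: a list with `genome`,
#'   `genes`, `sites` (simulation truth, if simulated), `chip_reads`,
#'   `input_reads`, `extended`, `peaks`, `annotations`, `distribution`,
#'   `profiles` (per-zone `metagene_profile`s), `motif`, `enrichment`,
#'   `manifest` and `config`.
#' @export
run_chipscape <- function(config = chipscape_config()) {
  stopifnot(inherits(config, "chipscape_config"))
  if (config$simulate) {
    sim <- simulate_chip_experiment(
      genome_length = config$genome_length, n_genes = config$n_genes,
      plan = config$plan, placement = config$placement,
      config = config$sim_config, seed = config$seed)
    genome <- sim$genome; genes <- sim$genes; sites <- sim$sites
    chip <- sim$chip_reads; input <- sim$input_reads
    clen <- sim$chrom_lengths
  } else {
    genome <- read_genome_fasta(config$genome_path)
    genes <- read_gene_models(config$genes_path)
    chip <- read_reads_bed(config$chip_path)
    input <- read_reads_bed(config$input_path)
    sites <- NULL
    clen <- chrom_lengths(names(genome), nchar(genome))
  }

  chip_ext <- extend_reads(chip, config$extend, clen)
  input_ext <- extend_reads(input, config$extend, clen)
  chip_cov <- window_coverage(chip_ext, clen, config$window)
  input_cov <- window_coverage(input_ext, clen, config$window)
  peaks <- call_enriched_regions(chip_cov, input_cov, config$caller)

  regions <- genic_regions(genes, clen, config$upstream, config$downstream)
  annotations <- classify_peaks(peaks, regions)
  distribution <- if (nrow(annotations) > 0) {
    summarize_distribution(annotations)
  }

  profiles <- list()
  for (zone in c("promoter", "gene_body", "downstream")) {
    profiles[[zone]] <- tryCatch(
      metagene_profile(chip_ext, regions, zone,
                       n_segments = config$n_segments),
      error = function(e) NULL)
  }

  motif <- NULL
  if (nrow(peaks) > 0) {
    gc <- if (identical(config$gc, "auto")) gc_fraction(genome) else config$gc
    motif <- motif_report(peak_sequences(peaks, genome), config$pattern,
                          composition_model(gc), config$strands)
  }

  enrichment <- NULL
  if (!is.null(config$categories)) {
    targets <- unique(annotations$gene_id[!is.na(annotations$gene_id)])
    if (length(targets) > 0) {
      N <- config$genome_size_genes %||% nrow(genes)
      enrichment <- enrich_categories(targets, config$categories, N)
    }
  }

  run <- structure(list(
    genome = genome, genes = genes, sites = sites,
    chip_reads = chip, input_reads = input, extended = chip_ext,
    chrom_lengths = clen, chip_coverage = chip_cov,
    input_coverage = input_cov, peaks = peaks,
    annotations = annotations, distribution = distribution,
    profiles = profiles, motif = motif, enrichment = enrichment,
    manifest = NULL, config = config), class = "chipscape_run")

  if (!is.null(config$outdir)) {
    run$manifest <- write_run_outputs(run, config$outdir)
  }
  run
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_genome_fasta(run$genome, p("genome.fa"))
  write_gene_models_gff3(run$genes, p("genes.gff3"))
  write_reads_bed(run$chip_reads, p("chip_reads.bed"))
  write_reads_bed(run$input_reads, p("input_reads.bed"))
  write_peaks_bed(run$peaks, p("peaks.bed"))
  write_report_tsv(run$peaks, p("peaks.tsv"))
  write_report_tsv(run$annotations, p("annotations.tsv"))
  if (!is.null(run$sites)) write_report_tsv(run$sites, p("planted_sites.tsv"))
  if (!is.null(run$distribution)) {
    write_report_tsv(run$distribution, p("distribution_summary.tsv"))
  }
  for (zone in names(run$profiles)) {
    if (!is.null(run$profiles[[zone]])) {
      write_report_tsv(tidy(run$profiles[[zone]]),
                       p(paste0("metagene_", zone, ".tsv")))
    }
  }
  if (!is.null(run$motif)) {
    jsonlite::write_json(as.list(as_tibble(run$motif)),
                         p("motif_stats.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$enrichment)) {
    write_report_tsv(run$enrichment, p("enrichment.tsv"))
  }
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    seed = run$config$seed,
    counts = list(chip_reads = nrow(run$chip_reads),
                  input_reads = nrow(run$input_reads),
                  peaks = nrow(run$peaks),
                  genes = nrow(run$genes)),
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' @export
print.chipscape_run <- function(x, ...) {
  cat("<chipscape_run>\n")
  cat(sprintf("  genome: %s (%s bp), %d genes\n",
              paste(names(x$genome), collapse = ","),
              format(sum(nchar(x$genome)), big.mark = ","), nrow(x$genes)))
  cat(sprintf("  reads: %d ChIP / %d input; peaks called: %d\n",
              nrow(x$chip_reads), nrow(x$input_reads), nrow(x$peaks)))
  if (!is.null(x$distribution)) {
    d <- x$distribution
    cat(sprintf("  genic peaks: %d/%d (%d%%); promoter/body/downstream = %d/%d/%d%%\n",
                d$n_genic, d$n_peaks, d$pct_genic, d$pct_promoter,
                d$pct_gene_body, d$pct_downstream))
  }
  if (!is.null(x$motif)) {
    cat(sprintf("  motif %s: observed %.3g /bp vs expected %.3g /bp (%.1f-fold)\n",
                x$motif$pattern, x$motif$observed_freq,
                x$motif$expected_freq, x$motif$fold))
  }
  invisible(x)
}
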