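#' Zero-order base composition model
#'
#' Bases are drawn independently with `p(G) = p(C) = gc/2` and
#' `p(A) = p(T) = (1 - gc)/2`. The default 0.332 is the GC content of the
#' tomato nuclear genome, the background against which consensus-motif
#' frequencies are judged.
#'
#' @param gc GC fraction, strictly between 0 and 1.
#' @return An object of class `composition_model`: a named probability
#'   vector over A, C, G, T plus the `gc` attribute.
#' @export
composition_model <- function(gc = 0.332) {
  if (!is.numeric(gc) || length(gc) != 1 || is.na(gc) || gc <= 0 || gc >= 1) {
    abort("gc fraction must be a single number strictly between 0 and 1")
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  structure(probs, gc = gc, class = "composition_model")
}

# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random genome sequence
#'
#' Draws `length` i.i.d. bases from a [composition_model()]. The same seed
#' and composition always give the same sequence; the caller's RNG state is
#' left untouched.
#'
#' @param length Genome length in bp (>= 1).
#' @param composition A [composition_model()].
#' @param seed Integer seed.
#' @param chrom Chromosome name for the single generated sequence.
#' @return Named character vector of length one (the sequence).
#' @export
generate_genome <- function(length, composition = composition_model(),
                            seed = 1L, chrom = "chr1") {
  stopifnot(inherits(composition, "composition_model"), length >= 1)
  seq <- with_seed(seed, {
    paste(sample(names(composition), size = length, replace = TRUE,
                 prob = as.numeric(composition)), collapse = "")
  })
  setNames(seq, chrom)
}

#' Measured GC fraction of a sequence
#'
#' @param genome Named character vector of sequences.
#' @return Fraction of G+C bases over all non-N bases.
#' @export
gc_fraction <- function(genome) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(genome))
  counts <- colSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  unname((counts["G"] + counts["C"]) / sum(counts))
}

#' Generate non-overlapping stranded gene models
#'
#' Genes are packed left to right with enough spacing that, when
#' `non_overlapping_genic_regions = TRUE`, every gene's genic region
#' (`upstream` bp before the TSS through `downstream` bp past the TES) is
#' disjoint from its neighbours'. Each gene gets 1-5 exons with the first
#' and last exon flush with the gene ends. Packing that cannot fit raises
#' an error rather than silently dropping genes.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_genes Number of genes to place.
#' @param length_range Two-element range of gene lengths in bp.
#' @param upstream,downstream Genic-region extents in bp (defaults 3000 and
#'   1000).
#' @param non_overlapping_genic_regions Reserve the full genic region per
#'   gene when packing.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return A gene-model tibble (see [read_gene_models()]).
#' @export
generate_gene_models <- function(genome_length, n_genes,
                                 length_range = c(1500L, 3000L),
                                 upstream = 3000L, downstream = 1000L,
                                 non_overlapping_genic_regions = TRUE,
                                 seed = 1L, chrom = "chr1") {
  stopifnot(n_genes >= 1, length_range[1] >= 200,
            length_range[2] >= length_range[1])
  with_seed(seed, {
    gene_len <- sample(seq(length_range[1], length_range[2]), n_genes,
                       replace = TRUE)
    pad <- if (non_overlapping_genic_regions) upstream + downstream else 0L
    slot_len <- gene_len + pad
    spare <- genome_length - sum(slot_len) - (n_genes + 1L)
    if (spare < 0) {
      abort(sprintf(
        "cannot pack %d genes (plus genic-region padding) into %d bp",
        n_genes, genome_length))
    }
    # distribute spare bp into n_genes + 1 gaps via sorted uniform breaks
    breaks <- sort(sample.int(spare + 1L, n_genes, replace = TRUE) - 1L)
    gaps <- diff(c(0L, breaks, spare)) + 1L
    slot_start <- cumsum(gaps[seq_len(n_genes)]) +
      c(0L, cumsum(slot_len))[seq_len(n_genes)] + 1L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    up_pad <- if (non_overlapping_genic_regions) upstream else 0L
    dn_pad <- if (non_overlapping_genic_regions) downstream else 0L
    g_start <- ifelse(strand == "+", slot_start + up_pad, slot_start + dn_pad)
    g_end <- g_start + gene_len - 1L
    genes <- tibble(
      gene_id = sprintf("gene%03d", seq_len(n_genes)),
      chrom = chrom,
      start = as.integer(g_start),
      end = as.integer(g_end),
      strand = strand)
    genes$exons <- map2(genes$start, genes$end, function(s, e) {
      random_exons(s, e)
    })
    validate_gene_models(genes)
  })
}

# split [s, e] into k exons / k-1 introns; outermost segments are exons
random_exons <- function(s, e, max_exons = 5L) {
  len <- e - s + 1L
  k <- sample.int(max_exons, 1L)
  n_seg <- 2L * k - 1L
  if (n_seg >= len) k <- 1L
  if (k == 1L) return(tibble(start = s, end = e))
  cuts <- sort(sample(seq_len(len - 1L), 2L * k - 2L))
  seg_start <- s + c(0L, cuts)
  seg_end <- c(s + cuts - 1L, e)
  idx <- seq(1L, 2L * k - 1L, by = 2L)
  tibble(start = as.integer(seg_start[idx]), end = as.integer(seg_end[idx]))
}

#' Plant consensus motif sites into a genome
#'
#' Writes concrete instances of a degenerate IUPAC pattern (default the
#' ASR1 consensus `WRGCCCA`) into the requested genic zones. Each site gets
#' a random strand; reverse-strand sites appear as the reverse complement
#' on the forward genome sequence. Sites never overlap one another, and
#' each site's zone label is re-derivable by [classify_peaks()] on the
#' planted interval.
#'
#' @param genome Named character vector (single chromosome).
#' @param genes Gene-model tibble.
#' @param plan Named integer vector of site counts per zone, names among
#'   `promoter`, `gene_body`, `downstream`, `intergenic`.
#' @param pattern IUPAC pattern string to plant.
#' @param placement `"center"` plants each site at its zone's midpoint,
#'   `"uniform"` at a uniform position within the zone.
#' @param upstream,downstream Genic-region extents (must match the
#'   downstream annotation call).
#' @param seed Integer seed.
#' @return A list with elements `genome` (modified sequence) and `sites`
#'   (tibble: `chrom`, `start`, `end`, `strand`, `zone`, `gene_id`,
#'   `sequence`).
#' @export
plant_sites <- function(genome, genes, plan, pattern = "WRGCCCA",
                        placement = c("center", "uniform"),
                        upstream = 3000L, downstream = 1000L, seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(length(genome) == 1, !is.null(names(plan)))
  bad <- setdiff(names(plan), c("promoter", "gene_body", "downstream",
                                "intergenic"))
  if (length(bad)) abort(paste("unknown zone label(s):", paste(bad, collapse = ", ")))
  pat <- compile_pattern(pattern)
  m <- pat$length
  chrom <- names(genome)
  glen <- nchar(genome)
  clen <- chrom_lengths(chrom, glen)
  zones <- genic_regions(genes, clen, upstream = upstream,
                         downstream = downstream)
  with_seed(seed, {
    placed <- list()
    occupied <- tibble(chrom = character(), start = integer(), end = integer())
    for (zone in names(plan)) {
      count <- plan[[zone]]
      if (count == 0) next
      if (zone == "intergenic") {
        for (i in seq_len(count)) {
          pos <- sample_intergenic_start(glen, m, zones, occupied)
          placed[[length(placed) + 1]] <- tibble(
            chrom = chrom, start = pos, end = pos + m - 1L,
            zone = zone, gene_id = NA_character_)
          occupied <- bind_rows(occupied, placed[[length(placed)]][1:3])
        }
      } else {
        cand <- filter(zones, .data$zone == .env$zone,
                       .data$end - .data$start + 1L >= m)
        if (nrow(cand) < count) {
          abort(sprintf("only %d genes can host a %s site; %d requested",
                        nrow(cand), zone, count))
        }
        cand <- slice(cand, sample.int(nrow(cand), count))
        for (i in seq_len(count)) {
          if (placement == "center") {
            mid <- midpoint_position(cand$start[i], cand$end[i])
            pos <- as.integer(mid - m %/% 2L)
          } else {
            pos <- cand$start[i] +
              sample.int(cand$end[i] - cand$start[i] - m + 2L, 1L) - 1L
          }
          placed[[length(placed) + 1]] <- tibble(
            chrom = chrom, start = pos, end = pos + m - 1L,
            zone = zone, gene_id = cand$gene_id[i])
        }
      }
    }
    sites <- bind_rows(placed)
    if (nrow(sites) == 0) {
      return(list(genome = genome,
                  sites = tibble(chrom = character(), start = integer(),
                                 end = integer(), zone = character(),
                                 gene_id = character(), strand = character(),
                                 sequence = character())))
    }
    if (any(duplicated_overlaps(sites))) {
      abort("planted sites overlap; reduce counts or enlarge the genome")
    }
    sites$strand <- sample(c("+", "-"), nrow(sites), replace = TRUE)
    sites$sequence <- map_chr(seq_len(nrow(sites)), function(i) {
      paste(map_chr(pat$sets, function(b) sample(b, 1L)), collapse = "")
    })
    seq <- genome[[1]]
    for (i in seq_len(nrow(sites))) {
      ins <- if (sites$strand[i] == "+") sites$sequence[i] else
        reverse_complement(sites$sequence[i])
      substr(seq, sites$start[i], sites$end[i]) <- ins
    }
    list(genome = setNames(seq, chrom),
         sites = validate_intervals(sites, what = "planted site"))
  })
}

sample_intergenic_start <- function(glen, m, zones, occupied, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    pos <- sample.int(glen - m + 1L, 1L)
    cand <- tibble(chrom = zones$chrom[1] %||% "chr1",
                   start = pos, end = pos + m - 1L)
    hit_zone <- nrow(zones) > 0 &&
      any(intervals_overlap(cand, zones[, c("chrom", "start", "end")]))
    hit_occ <- nrow(occupied) > 0 && any(intervals_overlap(cand, occupied))
    if (!hit_zone && !hit_occ) return(pos)
  }
  abort("no intergenic room left to plant a site")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

duplicated_overlaps <- function(iv) {
  n <- nrow(iv)
  if (n < 2) return(logical(n))
  out <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (intervals_overlap(iv[i, ], iv[j, ])) out[j] <- TRUE
    }
  }
  out
}

#' Simulation configuration
#'
#' Holds the fragment/read geometry and depth parameters of the simulated
#' ChIP experiment. Defaults mirror the modelled experiment: ~400 bp
#' sonicated fragments sequenced as 51 nt single-end reads.
#'
#' @param fragment_length Mean fragment length in bp.
#' @param read_length Sequenced read length in bp (<= `fragment_length`).
#' @param enrichment Expected ChIP fragments per planted site (Poisson
#'   mean).
#' @param background_depth Expected background fragments per bp (Poisson
#'   rate), for both the ChIP and input libraries.
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(fragment_length = 400L, read_length = 51L,
                              enrichment = 50, background_depth = 0.01,
                              seed = 1L) {
  stopifnot(fragment_length >= read_length, read_length >= 1,
            enrichment >= 0, background_depth >= 0)
  structure(list(fragment_length = as.integer(fragment_length),
                 read_length = as.integer(read_length),
                 enrichment = enrichment,
                 background_depth = background_depth,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate ChIP and input reads
#'
#' For each planted site, `Poisson(enrichment)` fragments are generated
#' with midpoints normally scattered around the site centre
#' (sd = `fragment_length / 4`); background fragments arrive as a uniform
#' Poisson process at `background_depth` per bp. Every fragment yields one
#' read of `read_length` bp from a uniformly chosen end: forward-strand
#' reads from the left end, reverse-strand reads from the right end, the
#' standard single-end ChIP geometry. Reads are clamped to the chromosome.
#' `simulate_input_reads()` is the background-only control.
#'
#' @param genome Named character vector (single chromosome).
#' @param sites Planted-site tibble from [plant_sites()] (may have 0 rows).
#' @param config A [simulation_config()].
#' @return A read tibble (`chrom`, `start`, `end`, `strand`, `name`).
#' @export
simulate_chip_reads <- function(genome, sites, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"), length(genome) == 1)
  chrom <- names(genome)
  glen <- nchar(genome[[1]])
  with_seed(config$seed, {
    mids <- numeric(0)
    if (nrow(sites) > 0 && config$enrichment > 0) {
      centers <- midpoint_position(sites$start, sites$end)
      n_frag <- rpois(length(centers), config$enrichment)
      mids <- rnorm(sum(n_frag), mean = rep(centers, n_frag),
                    sd = config$fragment_length / 4)
    }
    n_bg <- rpois(1L, config$background_depth * glen)
    mids <- c(mids, runif(n_bg, min = 1, max = glen))
    fragments_to_reads(mids, chrom, glen, config)
  })
}

#' @rdname simulate_chip_reads
#' @export
simulate_input_reads <- function(genome, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"), length(genome) == 1)
  chrom <- names(genome)
  glen <- nchar(genome[[1]])
  with_seed(config$seed, {
    n_bg <- rpois(1L, config$background_depth * glen)
    mids <- runif(n_bg, min = 1, max = glen)
    fragments_to_reads(mids, chrom, glen, config)
  })
}

fragments_to_reads <- function(mids, chrom, glen, config) {
  n <- length(mids)
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character()))
  }
  fl <- config$fragment_length
  rl <- config$read_length
  fs <- pmax(1L, pmin(as.integer(round(mids)) - fl %/% 2L, glen))
  fe <- pmin(glen, fs + fl - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", fs, pmax(1L, fe - rl + 1L))
  end <- ifelse(strand == "+", pmin(glen, fs + rl - 1L), fe)
  validate_reads(tibble(
    chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    strand = strand,
    name = sprintf("frag%06d", seq_len(n))))
}

#' Simulate a complete ChIP experiment
#'
#' Convenience wrapper that generates a genome, gene models, planted sites
#' and matched ChIP/input read sets in one call. Per-stage seeds are
#' derived from the root `seed` by fixed small offsets (genome +1, genes
#' +2, sites +3, ChIP reads +4, input reads +5), so each stage is
#' independently reproducible.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of genes.
#' @param plan Planting plan (see [plant_sites()]).
#' @param gc Background GC fraction.
#' @param placement Site placement within zones (see [plant_sites()]).
#' @param config A [simulation_config()]; its `seed` field is overridden by
#'   the derived stage seeds.
#' @param seed Root integer seed.
#' @return A list: `genome`, `genes`, `sites`, `chip_reads`, `input_reads`,
#'   `chrom_lengths`, `config`, `seed`.
#' @export
simulate_chip_experiment <- function(genome_length = 150000L, n_genes = 20L,
                                     plan = c(promoter = 5L, gene_body = 5L),
                                     gc = 0.332,
                                     placement = "center",
                                     config = simulation_config(),
                                     seed = 1L) {
  seed <- as.integer(seed)
  genome <- generate_genome(genome_length, composition_model(gc), seed = seed + 1L)
  genes <- generate_gene_models(genome_length, n_genes, seed = seed + 2L)
  planted <- plant_sites(genome, genes, plan, placement = placement,
                         seed = seed + 3L)
  chip_cfg <- config; chip_cfg$seed <- seed + 4L
  input_cfg <- config; input_cfg$seed <- seed + 5L
  list(genome = planted$genome,
       genes = genes,
       sites = planted$sites,
       chip_reads = simulate_chip_reads(planted$genome, planted$sites, chip_cfg),
       input_reads = simulate_input_reads(planted$genome, input_cfg),
       chrom_lengths = chrom_lengths(names(genome), genome_length),
       config = config,
       seed = seed)
}
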