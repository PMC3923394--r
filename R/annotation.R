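#' Genic regions: promoter, gene body, downstream
#'
#' The genic region of a gene spans from `upstream` bp (default 3,000)
#' before the transcription start site to `downstream` bp (default 1,000)
#' past the transcription end site, strand-aware. It is partitioned into
#' three abutting zones: `promoter` (upstream of the TSS), `gene_body`
#' (TSS..TES, i.e. exons plus introns) and `downstream`. Zones are clamped
#' at chromosome ends; a zone clamped to nothing is dropped.
#'
#' @param genes Gene-model tibble.
#' @param chrom_lengths A [chrom_lengths()] tibble.
#' @param upstream Promoter extent in bp.
#' @param downstream Downstream extent in bp.
#' @return A long tibble, one row per gene x zone: `gene_id`, `chrom`,
#'   `strand`, `zone`, `start`, `end`, `tss`, `tes`.
#' @export
genic_regions <- function(genes, chrom_lengths, upstream = 3000L,
                          downstream = 1000L) {
  genes <- validate_gene_models(genes)
  clen <- chrom_length_of(chrom_lengths, genes$chrom)
  fwd <- genes$strand == "+"
  tss <- ifelse(fwd, genes$start, genes$end)
  tes <- ifelse(fwd, genes$end, genes$start)
  prom_start <- ifelse(fwd, genes$start - upstream, genes$end + 1L)
  prom_end <- ifelse(fwd, genes$start - 1L, genes$end + upstream)
  down_start <- ifelse(fwd, genes$end + 1L, genes$start - downstream)
  down_end <- ifelse(fwd, genes$end + downstream, genes$start - 1L)
  zones <- bind_rows(
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, zone = "promoter",
           start = as.integer(prom_start), end = as.integer(prom_end),
           tss = as.integer(tss), tes = as.integer(tes), clen = clen),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, zone = "gene_body",
           start = genes$start, end = genes$end,
           tss = as.integer(tss), tes = as.integer(tes), clen = clen),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           strand = genes$strand, zone = "downstream",
           start = as.integer(down_start), end = as.integer(down_end),
           tss = as.integer(tss), tes = as.integer(tes), clen = clen))
  zones |>
    mutate(start = pmax(.data$start, 1L),
           end = pmin(.data$end, .data$clen)) |>
    filter(.data$start <= .data$end) |>
    select(-"clen") |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Classify peaks into genic zones
#'
#' Each peak is represented by a single anchor point — its summit when
#' present, otherwise the interval midpoint — and classified by the zone
#' containing that anchor. When the anchor falls inside the genic regions
#' of several genes, the gene whose TSS is nearest wins; remaining ties go
#' to the lexicographically smallest `gene_id`. An anchor in no genic
#' region is `intergenic`. Single-point classification makes the four
#' labels a partition, so zone percentages sum to 100.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `summit`).
#' @param regions Output of [genic_regions()].
#' @return Annotation tibble: the peak columns plus `anchor`, `zone`,
#'   `gene_id` (NA iff intergenic) and `distance_to_tss`.
#' @export
classify_peaks <- function(peaks, regions) {
  peaks <- validate_intervals(peaks, what = "peak")
  anchor <- if ("summit" %in% names(peaks) && !all(is.na(peaks$summit))) {
    as.integer(ifelse(is.na(peaks$summit),
                      midpoint_position(peaks$start, peaks$end),
                      peaks$summit))
  } else {
    midpoint_position(peaks$start, peaks$end)
  }
  res <- map(seq_len(nrow(peaks)), function(i) {
    hit <- regions[regions$chrom == peaks$chrom[i] &
                     regions$start <= anchor[i] &
                     regions$end >= anchor[i], ]
    if (nrow(hit) == 0) {
      return(tibble(zone = "intergenic", gene_id = NA_character_,
                    distance_to_tss = NA_integer_))
    }
    hit <- hit[order(abs(hit$tss - anchor[i]), hit$gene_id), ]
    tibble(zone = hit$zone[1], gene_id = hit$gene_id[1],
           distance_to_tss = as.integer(abs(hit$tss[1] - anchor[i])))
  })
  peaks$anchor <- anchor
  dplyr::bind_cols(peaks, bind_rows(res))
}

#' Summarize the genomic distribution of annotated peaks
#'
#' Reports the fraction of peaks falling in genic regions and, among those,
#' the split between promoter, gene body and downstream zones — the
#' genome-wide binding-preference summary. Percentages are reported
#' rounded to integers alongside the exact fractions.
#'
#' @param annotations Output of [classify_peaks()].
#' @return A one-row tibble: `n_peaks`, `n_genic`, `fraction_genic`,
#'   `pct_genic`, then per-zone among-genic fractions
#'   (`frac_promoter`, `frac_gene_body`, `frac_downstream`) and integer
#'   percentages (`pct_promoter`, ...). Among-genic columns are `NA` when
#'   no peak is genic.
#' @export
summarize_distribution <- function(annotations) {
  if (nrow(annotations) == 0) abort("no annotated peaks to summarize")
  n <- nrow(annotations)
  genic <- annotations$zone != "intergenic"
  n_genic <- sum(genic)
  zone_n <- function(z) sum(annotations$zone == z)
  frac <- function(z) if (n_genic > 0) zone_n(z) / n_genic else NA_real_
  tibble(
    n_peaks = n,
    n_genic = n_genic,
    fraction_genic = n_genic / n,
    pct_genic = round(100 * n_genic / n),
    frac_promoter = frac("promoter"),
    frac_gene_body = frac("gene_body"),
    frac_downstream = frac("downstream"),
    pct_promoter = round(100 * frac("promoter")),
    pct_gene_body = round(100 * frac("gene_body")),
    pct_downstream = round(100 * frac("downstream")))
}
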