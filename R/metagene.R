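#' Per-gene, per-zone coverage totals
#'
#' For every gene x zone row of [genic_regions()], sums the number of bases
#' by which the supplied intervals (extended reads) overlap the zone. These
#' totals drive zone-specific gene selection for metagene averaging.
#'
#' @param intervals Interval tibble (extended reads).
#' @param regions Output of [genic_regions()].
#' @return `regions` with an added `coverage_bp` column.
#' @export
zone_coverage_totals <- function(intervals, regions) {
  intervals <- validate_intervals(intervals)
  regions$coverage_bp <- map_dbl(seq_len(nrow(regions)), function(i) {
    iv <- intervals[intervals$chrom == regions$chrom[i], ]
    if (nrow(iv) == 0) return(0)
    ov <- pmin(iv$end, regions$end[i]) - pmax(iv$start, regions$start[i]) + 1
    sum(pmax(ov, 0))
  })
  regions
}

#' Select genes giving reads mainly in one zone
#'
#' A gene qualifies for the metagene average of a zone when more than
#' `majority_threshold` of its genic-region coverage falls in that zone
#' ("mainly" formalised as a majority). Genes with zero coverage qualify
#' for no zone.
#'
#' @param zone_totals Output of [zone_coverage_totals()].
#' @param zone One of `"promoter"`, `"gene_body"`, `"downstream"`.
#' @param majority_threshold Coverage fraction a zone must exceed
#'   (default 0.5).
#' @return Character vector of selected `gene_id`s.
#' @export
select_genes_for_zone <- function(zone_totals, zone,
                                  majority_threshold = 0.5) {
  stopifnot(zone %in% c("promoter", "gene_body", "downstream"))
  per_gene <- zone_totals |>
    group_by(.data$gene_id) |>
    summarise(total = sum(.data$coverage_bp),
              in_zone = sum(.data$coverage_bp[.data$zone == .env$zone]),
              .groups = "drop") |>
    filter(.data$total > 0,
           .data$in_zone / .data$total > majority_threshold)
  sort(per_gene$gene_id)
}

#' Raw 100-segment coverage profile of one zone
#'
#' The zone interval is subdivided into `n_segments` consecutive
#' near-equal slices; when the length is not divisible, the first
#' `length %% n_segments` segments get the extra base. An interval
#' increments every segment it overlaps. The vector is reported 5' to 3'
#' in gene orientation, so it is reversed for reverse-strand genes. Zones
#' shorter than `n_segments` produce zero-width segments, which stay at
#' zero.
#'
#' @param intervals Interval tibble (extended reads).
#' @param chrom,start,end The zone interval.
#' @param strand Gene strand, `"+"` or `"-"`.
#' @param n_segments Number of segments (default 100).
#' @return Integer vector of length `n_segments`.
#' @export
gene_profile <- function(intervals, chrom, start, end, strand = "+",
                         n_segments = 100L) {
  intervals <- validate_intervals(intervals)
  stopifnot(end >= start, n_segments >= 1, strand %in% c("+", "-"))
  L <- end - start + 1L
  widths <- segment_widths(L, n_segments)
  cum <- cumsum(widths)
  bounds <- c(0, cum)
  counts <- integer(n_segments)
  iv <- intervals[intervals$chrom == chrom &
                    intervals$start <= end & intervals$end >= start, ]
  for (i in seq_len(nrow(iv))) {
    a <- max(iv$start[i], start) - start + 1L
    b <- min(iv$end[i], end) - start + 1L
    ka <- findInterval(a - 0.5, bounds)
    kb <- findInterval(b - 0.5, bounds)
    ks <- ka:kb
    ks <- ks[widths[ks] > 0L]
    counts[ks] <- counts[ks] + 1L
  }
  if (strand == "-") counts <- rev(counts)
  counts
}

segment_widths <- function(L, n_segments) {
  base <- L %/% n_segments
  extra <- L %% n_segments
  as.integer(base + (seq_len(n_segments) <= extra))
}

#' Normalize a gene's segment profile to its own maximum
#'
#' Each segment count is divided by the gene's maximum segment count, so
#' every contributing gene tops out at 1 and sequencing depth cancels. An
#' all-zero profile cannot be normalized: `NULL` is returned with a
#' warning, and the gene is skipped from averaging.
#'
#' @param raw Integer/numeric vector of segment counts.
#' @return Numeric vector with maximum 1, or `NULL` for all-zero input.
#' @export
normalize_gene_profile <- function(raw) {
  m <- max(raw)
  if (m <= 0) {
    warn("all-zero profile: gene skipped from metagene averaging")
    return(NULL)
  }
  raw / m
}

#' Average normalized profiles across genes
#'
#' Element-wise arithmetic mean of per-gene normalized segment vectors,
#' with equal weight per gene.
#'
#' @param profiles A list of equal-length numeric vectors (NULL entries,
#'   e.g. skipped all-zero genes, are dropped).
#' @param zone Optional zone label stored on the result.
#' @return A `metagene_profile` tibble: `segment`, `value`, with
#'   attributes `zone` and `n_genes`.
#' @export
average_profiles <- function(profiles, zone = NA_character_) {
  profiles <- profiles[!map_lgl(profiles, is.null)]
  if (length(profiles) == 0) abort("no profiles to average")
  lens <- unique(map_int(profiles, length))
  if (length(lens) != 1) abort("profiles must have equal length")
  mat <- do.call(rbind, profiles)
  out <- tibble(segment = seq_len(ncol(mat)), value = colMeans(mat))
  structure(out, zone = zone, n_genes = length(profiles),
            class = c("metagene_profile", class(out)))
}

#' Metagene average binding profile for a zone
#'
#' The full average-distribution computation: select the genes whose
#' coverage falls mainly in `zone`, bin each selected gene's zone into
#' `n_segments` consecutive segments (5' to 3'), normalize each gene to
#' its own maximum segment, and average across genes segment-wise.
#'
#' @param intervals Extended-read interval tibble.
#' @param regions Output of [genic_regions()].
#' @param zone `"promoter"`, `"gene_body"` or `"downstream"`.
#' @param majority_threshold Gene-selection threshold (see
#'   [select_genes_for_zone()]).
#' @param n_segments Number of segments (default 100).
#' @param gene_ids Optional explicit gene set, bypassing selection.
#' @return A `metagene_profile` tibble (`segment`, `value`) with
#'   attributes `zone`, `n_genes` and `gene_ids`.
#' @export
metagene_profile <- function(intervals, regions, zone,
                             majority_threshold = 0.5, n_segments = 100L,
                             gene_ids = NULL) {
  stopifnot(zone %in% c("promoter", "gene_body", "downstream"))
  if (is.null(gene_ids)) {
    totals <- zone_coverage_totals(intervals, regions)
    gene_ids <- select_genes_for_zone(totals, zone, majority_threshold)
  }
  rows <- regions[regions$zone == zone & regions$gene_id %in% gene_ids, ]
  if (nrow(rows) == 0) {
    abort(sprintf("no genes selected for zone %s", zone))
  }
  profiles <- map(seq_len(nrow(rows)), function(i) {
    raw <- gene_profile(intervals, rows$chrom[i], rows$start[i],
                        rows$end[i], rows$strand[i], n_segments)
    suppressWarnings(normalize_gene_profile(raw))
  })
  out <- average_profiles(profiles, zone = zone)
  attr(out, "gene_ids") <- sort(rows$gene_id[!map_lgl(profiles, is.null)])
  attr(out, "n_genes") <- length(attr(out, "gene_ids"))
  out
}
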