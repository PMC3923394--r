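#' Read and write genome sequences as FASTA
#'
#' Sequences are held internally as a named character vector, one element
#' per chromosome, uppercase A/C/G/T/N.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()`: named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(!is.null(names(genome)), all(nzchar(names(genome))))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), filepath = path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Consumes `gene` features (required) and `exon` features (optional,
#' attached by their `Parent` attribute). Coordinates stay 1-based closed as
#' in the file. The transcription start site (TSS) of a forward-strand gene
#' is its `start`; on the reverse strand it is its `end`.
#'
#' @param path GFF3 file path.
#' @return A gene-model tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` ("+" or "-"), and a list-column `exons` of tibbles
#'   (`start`, `end`, sorted by genome coordinate).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df) || !any(df$type == "gene")) {
    abort(sprintf("no `gene` features found in %s", path))
  }
  id_col <- if ("ID" %in% names(df)) df$ID else df$Name
  genes <- df |>
    mutate(gene_id = as.character(id_col)) |>
    filter(.data$type == "gene") |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand)) |>
    select("gene_id", "chrom", "start", "end", "strand")
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene features must be stranded (+ or -)")
  }
  exons <- df |> filter(.data$type == "exon")
  exon_list <- map(genes$gene_id, function(gid) {
    if (nrow(exons) == 0 || !"Parent" %in% names(exons)) {
      return(tibble(start = integer(), end = integer()))
    }
    hit <- map_lgl(exons$Parent, function(p) gid %in% as.character(p))
    exons[hit, c("start", "end")] |> arrange(.data$start) |> as_tibble()
  })
  genes$exons <- exon_list
  validate_gene_models(genes)
}

validate_gene_models <- function(genes) {
  genes <- validate_intervals(genes, what = "gene")
  stopifnot(all(genes$strand %in% c("+", "-")))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) next
    if (any(ex$start < genes$start[i]) || any(ex$end > genes$end[i])) {
      abort(sprintf("exons of gene %s extend outside the gene span",
                    genes$gene_id[i]))
    }
    if (is.unsorted(ex$start) || any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("exons of gene %s must be sorted and non-overlapping",
                    genes$gene_id[i]))
    }
  }
  genes
}

#' @rdname read_gene_models
#' @param genes A gene-model tibble.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  genes <- validate_gene_models(genes)
  genes <- arrange(genes, .data$chrom, .data$start)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id)
  rows <- list(gene_gr)
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) next
    rows[[length(rows) + 1]] <- GenomicRanges::GRanges(
      seqnames = genes$chrom[i],
      ranges = IRanges::IRanges(ex$start, ex$end),
      strand = genes$strand[i],
      type = "exon",
      ID = paste0(genes$gene_id[i], ".exon", seq_len(nrow(ex))),
      Parent = genes$gene_id[i])
  }
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Read aligned reads from BED6 or SAM
#'
#' BED uses 0-based half-open coordinates on disk; they are converted to the
#' internal 1-based closed convention at this boundary (a BED line
#' `chr1 0 100` becomes the interval `[1, 100]`). SAM is already 1-based;
#' only chromosome, position, aligned length and the strand flag are
#' consumed.
#'
#' @param path File path.
#' @return A read tibble: `chrom`, `start`, `end`, `strand`, `name`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as_tibble(as.data.frame(gr))
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "+"
  nm <- if ("name" %in% names(df)) as.character(df$name) else
    paste0("read", seq_len(nrow(df)))
  validate_reads(tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = strand,
    name = nm))
}

validate_reads <- function(reads) {
  reads <- validate_intervals(reads, what = "read")
  if (!"strand" %in% names(reads)) abort("reads need a strand column")
  if (any(!reads$strand %in% c("+", "-"))) abort("read strand must be + or -")
  reads
}

#' @rdname read_reads_bed
#' @export
read_reads_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "qwidth", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  validate_reads(tibble(
    chrom = as.character(res$rname),
    start = as.integer(res$pos),
    end = as.integer(res$pos + res$qwidth - 1L),
    strand = as.character(res$strand),
    name = as.character(res$qname)))
}

#' Write reads or peaks as BED6
#'
#' Output is sorted by chromosome then start, and converted from the
#' internal 1-based closed convention to BED's 0-based half-open one, so a
#' peak `[101, 200]` is written as `100 200`.
#'
#' @param reads A read tibble (needs `strand`).
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  reads <- validate_reads(reads) |> arrange(.data$chrom, .data$start, .data$end)
  nm <- if ("name" %in% names(reads)) reads$name else
    paste0("read", seq_len(nrow(reads)))
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand,
    name = nm, score = 0)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @param peaks A peak tibble (`chrom`, `start`, `end`, `score`, optional
#'   `summit`).
#' @export
write_peaks_bed <- function(peaks, path) {
  peaks <- validate_intervals(peaks, what = "peak") |>
    arrange(.data$chrom, .data$start, .data$end)
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(peaks$start, peaks$end),
    strand = "*",
    name = paste0("peak", seq_len(nrow(peaks))),
    score = score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as_tibble(as.data.frame(gr))
  validate_intervals(tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    score = if ("score" %in% names(df)) as.numeric(df$score) else 0),
    what = "peak")
}

#' Write a tibble as a deterministic TSV report
#'
#' Thin wrapper over [readr::write_tsv()] that first sorts by `chrom` and
#' `start` when those columns are present, so emitted reports are stable
#' across runs.
#'
#' @param x A tibble.
#' @param path Output path.
#' @export
write_report_tsv <- function(x, path) {
  if (all(c("chrom", "start") %in% names(x))) {
    x <- arrange(x, .data$chrom, .data$start)
  }
  readr::write_tsv(x, path)
  invisible(path)
}
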