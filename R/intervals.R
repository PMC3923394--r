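#' Genomic interval tibbles
#'
#' All coordinates in chipscape are 1-based and fully closed: an interval
#' `[start, end]` includes both endpoints, so its length is
#' `end - start + 1`. This is the convention of GFF3 and SAM; BED input and
#' output are converted at the file boundary (see [read_reads_bed()]).
#'
#' `genomic_intervals()` builds a validated interval tibble with columns
#' `chrom`, `start`, `end` (recycled to a common length). Extra columns
#' passed through `...` are kept, which is how reads (`strand`), peaks
#' (`score`, `summit`) and planted sites carry their payload.
#'
#' @param chrom Chromosome names (character).
#' @param start,end 1-based inclusive positions; `start >= 1`, `end >= start`.
#' @param ... Further columns (e.g. `strand`, `score`), recycled like
#'   [tibble::tibble()] columns.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("1", 82955709, 82956371) |> interval_length()
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  iv <- tibble(chrom = as.character(chrom),
               start = as.integer(round(start)),
               end = as.integer(round(end)),
               ...)
  validate_intervals(iv)
}

validate_intervals <- function(iv, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(iv))) {
    abort(paste0(what, " table must have columns chrom, start, end"))
  }
  bad <- which(is.na(iv$start) | is.na(iv$end) | iv$start < 1 | iv$end < iv$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s at row %d: start=%s end=%s (need 1 <= start <= end)",
      what, bad[1], iv$start[bad[1]], iv$end[bad[1]]))
  }
  as_tibble(iv)
}

#' Interval length under the 1-based closed convention
#'
#' Appends a `length` column equal to `end - start + 1`.
#'
#' @param intervals An interval tibble (see [genomic_intervals()]).
#' @return The input tibble with a `length` column.
#' @export
interval_length <- function(intervals) {
  intervals <- validate_intervals(intervals)
  mutate(intervals, length = .data$end - .data$start + 1L)
}

#' Interval midpoint
#'
#' Appends a `midpoint` column, `floor((start + end) / 2)`. For even-length
#' intervals the tie breaks toward `start`, so the midpoint of `[1, 4]` is 2.
#'
#' @inheritParams interval_length
#' @return The input tibble with a `midpoint` column.
#' @export
interval_midpoint <- function(intervals) {
  intervals <- validate_intervals(intervals)
  mutate(intervals, midpoint = midpoint_position(.data$start, .data$end))
}

midpoint_position <- function(start, end) {
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Pairwise interval overlap
#'
#' Closed-interval overlap test, vectorised over rows of `a` and `b`
#' (recycled). Two intervals overlap iff they share a chromosome and
#' `a$start <= b$end && b$start <= a$end`; touching endpoints count.
#' Intervals on different chromosomes never overlap.
#'
#' @param a,b Interval tibbles, recycled to a common number of rows.
#' @return A logical vector.
#' @export
intervals_overlap <- function(a, b) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    a$start[ai] <= b$end[bi] &
    b$start[bi] <= a$end[ai]
}

#' Chromosome length table
#'
#' @param chrom Chromosome names.
#' @param length Chromosome lengths in bp.
#' @return A tibble with columns `chrom`, `length`.
#' @export
chrom_lengths <- function(chrom, length) {
  stopifnot(length(chrom) == length(length), all(length >= 1))
  tibble(chrom = as.character(chrom), length = as.integer(length))
}

chrom_length_of <- function(chrom_lengths, chrom) {
  idx <- match(chrom, chrom_lengths$chrom)
  if (anyNA(idx)) {
    abort(sprintf("unknown chromosome: %s",
                  paste(unique(chrom[is.na(idx)]), collapse = ", ")))
  }
  chrom_lengths$length[idx]
}

clamp_intervals <- function(iv, chrom_lengths) {
  len <- chrom_length_of(chrom_lengths, iv$chrom)
  mutate(iv,
         start = pmax(.data$start, 1L),
         end = pmin(.data$end, len))
}
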