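#' Extend reads to fragment length
#'
#' Strand-aware extension of short sequenced reads (~51 nt) to the
#' sonicated fragment length (~400 nt): a forward read keeps its start and
#' grows its end to `start + target_length - 1`; a reverse read keeps its
#' end and grows its start to `end - target_length + 1`. Results are
#' clamped to `[1, chromosome length]`. Reads already at least
#' `target_length` long pass through unchanged.
#'
#' @param reads Read tibble (`chrom`, `start`, `end`, `strand`).
#' @param target_length Fragment length to extend to (default 400 bp).
#' @param chrom_lengths A [chrom_lengths()] tibble; unknown chromosomes in
#'   `reads` raise an error naming them.
#' @return A tibble of extended intervals with the input's columns.
#' @export
extend_reads <- function(reads, target_length = 400L, chrom_lengths) {
  reads <- validate_reads(reads)
  stopifnot(target_length >= 1)
  clen <- chrom_length_of(chrom_lengths, reads$chrom)
  long_enough <- (reads$end - reads$start + 1L) >= target_length
  new_start <- ifelse(reads$strand == "+", reads$start,
                      reads$end - target_length + 1L)
  new_end <- ifelse(reads$strand == "+", reads$start + target_length - 1L,
                    reads$end)
  reads$start <- as.integer(ifelse(long_enough, reads$start,
                                   pmax(1L, new_start)))
  reads$end <- as.integer(ifelse(long_enough, reads$end,
                                 pmin(clen, new_end)))
  reads
}

#' Count interval coverage in fixed windows
#'
#' Tiles each chromosome with consecutive `window_size` bp windows starting
#' at position 1 (window *k* spans `[(k-1)*w + 1, k*w]`, the last window
#' clipped to the chromosome end) and counts, for every window, the number
#' of intervals overlapping it. An interval spanning a window boundary
#' increments both windows.
#'
#' @param intervals Interval tibble (typically extended reads).
#' @param chrom_lengths A [chrom_lengths()] tibble; every chromosome listed
#'   gets a full set of windows even with no reads.
#' @param window_size Window width in bp (default 150).
#' @return A tibble: `chrom`, `window` (1-based index), `start`, `end`,
#'   `count`.
#' @export
window_coverage <- function(intervals, chrom_lengths, window_size = 150L) {
  intervals <- validate_intervals(intervals)
  stopifnot(window_size >= 1)
  if (nrow(intervals) > 0) chrom_length_of(chrom_lengths, intervals$chrom)
  out <- map(seq_len(nrow(chrom_lengths)), function(ci) {
    chrom <- chrom_lengths$chrom[ci]
    clen <- chrom_lengths$length[ci]
    n_win <- as.integer(ceiling(clen / window_size))
    counts <- integer(n_win)
    iv <- filter(intervals, .data$chrom == .env$chrom)
    if (nrow(iv) > 0) {
      w1 <- pmin(n_win, (pmax(iv$start, 1L) - 1L) %/% window_size + 1L)
      w2 <- pmin(n_win, (pmin(iv$end, clen) - 1L) %/% window_size + 1L)
      # difference-array accumulation of [w1, w2] increments
      delta <- integer(n_win + 1L)
      for (i in seq_along(w1)) {
        delta[w1[i]] <- delta[w1[i]] + 1L
        delta[w2[i] + 1L] <- delta[w2[i] + 1L] - 1L
      }
      counts <- cumsum(delta[seq_len(n_win)])
    }
    tibble(chrom = chrom,
           window = seq_len(n_win),
           start = (seq_len(n_win) - 1L) * as.integer(window_size) + 1L,
           end = pmin(seq_len(n_win) * as.integer(window_size), clen),
           count = as.integer(counts))
  })
  bind_rows(out)
}

#' Enrichment-caller parameters
#'
#' Settings for the Poisson sample-versus-input caller in
#' [call_enriched_regions()].
#'
#' @param p_threshold Per-window significance level (in (0, 1)).
#' @param min_windows Minimum run of adjacent significant windows that
#'   forms a peak.
#' @param pseudocount Added to the scaled input count so empty input
#'   windows still define a finite Poisson mean.
#' @param scale Library-size factor multiplying the input counts; `NULL`
#'   (default) uses total-ChIP / total-input computed from the data.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(p_threshold = 1e-5, min_windows = 2L,
                          pseudocount = 1, scale = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1, min_windows >= 1,
            pseudocount >= 0)
  structure(list(p_threshold = p_threshold,
                 min_windows = as.integer(min_windows),
                 pseudocount = pseudocount, scale = scale),
            class = "caller_params")
}

#' Call enriched regions from windowed ChIP versus input coverage
#'
#' A deliberately simple stand-in for a full peak caller, honouring the
#' contract that peaks are regions with many reads in the ChIP sample but
#' not in the input control. Each window's ChIP count is tested against a
#' Poisson mean of `scale * (input count + pseudocount)` with an upper-tail
#' p-value; runs of at least `min_windows` adjacent significant windows on
#' a chromosome merge into one peak. The peak score is
#' `-10 * log10(min window p-value)` truncated to one decimal, and the
#' summit is the midpoint of the run's highest-count window.
#'
#' @param chip,input Window-coverage tibbles from [window_coverage()] on
#'   the same window grid.
#' @param params A [caller_params()].
#' @return A peak tibble: `chrom`, `start`, `end`, `score`, `summit`,
#'   `n_windows`, `max_count`.
#' @export
call_enriched_regions <- function(chip, input, params = caller_params()) {
  if (!identical(chip[, c("chrom", "window", "start", "end")],
                 input[, c("chrom", "window", "start", "end")])) {
    abort("chip and input coverage must share the same window grid")
  }
  scale <- params$scale
  if (is.null(scale)) {
    tot_in <- sum(input$count)
    scale <- if (tot_in > 0) sum(chip$count) / tot_in else 1
  }
  lambda <- scale * (input$count + params$pseudocount)
  # upper tail P(X >= k) in log space so extreme windows keep finite scores
  log10p <- ppois(chip$count - 1L, lambda, lower.tail = FALSE,
                  log.p = TRUE) / log(10)
  signif <- log10p < log10(params$p_threshold)
  peaks <- list()
  for (ch in unique(chip$chrom)) {
    idx <- which(chip$chrom == ch)
    r <- rle(signif[idx])
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_windows)) {
      win <- idx[run_start[k]:run_end[k]]
      best <- win[which.max(chip$count[win])]
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = ch,
        start = chip$start[win[1]],
        end = chip$end[win[length(win)]],
        score = trunc(-10 * min(log10p[win]) * 10) / 10,
        summit = midpoint_position(chip$start[best], chip$end[best]),
        n_windows = length(win),
        max_count = max(chip$count[win]))
    }
  }
  if (length(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  score = numeric(), summit = integer(),
                  n_windows = integer(), max_count = integer()))
  }
  bind_rows(peaks) |> arrange(.data$chrom, .data$start)
}
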