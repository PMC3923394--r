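IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC degenerate alphabet, so the reverse complement
#' of the consensus `WRGCCCA` is `TGGGCYW`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  map_chr(x, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
    if (length(bad)) abort(paste("not a IUPAC base:", paste(bad, collapse = ", ")))
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  })
}

#' Compile a degenerate IUPAC pattern
#'
#' Expands each pattern position into its allowed-base set and
#' precomputes the reverse-complement matcher. The default consensus
#' `WRGCCCA` reads (A/T)(A/G)GCCCA and expands to four concrete 7-mers.
#'
#' @param iupac Pattern string over the 15-letter IUPAC alphabet.
#' @return An object of class `motif_pattern`: `iupac`, `length`, `sets`
#'   (per-position allowed bases), `rc_sets` (the reverse-complement
#'   pattern's sets) and `n_expansions`.
#' @export
compile_pattern <- function(iupac = "WRGCCCA") {
  if (inherits(iupac, "motif_pattern")) return(iupac)
  stopifnot(is.character(iupac), length(iupac) == 1, nzchar(iupac))
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("illegal IUPAC character '%s' at position %d",
                  chars[bad[1]], bad[1]))
  }
  sets <- IUPAC_SETS[chars]
  rc_chars <- strsplit(reverse_complement(paste(chars, collapse = "")), "")[[1]]
  structure(list(iupac = toupper(iupac),
                 length = length(chars),
                 sets = unname(sets),
                 rc_sets = unname(IUPAC_SETS[rc_chars]),
                 n_expansions = prod(map_int(sets, length))),
            class = "motif_pattern")
}

scan_sets <- function(chars, sets) {
  n <- length(chars)
  m <- length(sets)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(n - m + j)] %in% sets[[j]]
  }
  which(ok)
}

#' Locate motif hits in one sequence
#'
#' Returns the 1-based offsets of all (overlapping) matches. In
#' both-strand mode the reverse-complement pattern is also matched at
#' every offset of the forward sequence, which is equivalent to scanning
#' the minus strand. `N` bases match nothing.
#'
#' @param sequence A single DNA string.
#' @param pattern IUPAC string or [compile_pattern()] object.
#' @param strands `"both"` (default) or `"forward"`.
#' @return A tibble: `offset` (start of match on the forward sequence),
#'   `strand`.
#' @export
hit_positions <- function(sequence, pattern = "WRGCCCA",
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  pat <- compile_pattern(pattern)
  chars <- strsplit(toupper(sequence), "")[[1]]
  fwd <- scan_sets(chars, pat$sets)
  out <- tibble(offset = fwd, strand = rep("+", length(fwd)))
  if (strands == "both") {
    rev_hits <- scan_sets(chars, pat$rc_sets)
    out <- bind_rows(out, tibble(offset = rev_hits,
                                 strand = rep("-", length(rev_hits))))
  }
  arrange(out, .data$offset, .data$strand)
}

#' Count motif hits over a set of sequences
#'
#' Overlapping occurrences are all counted; `total_bp` is the summed
#' sequence length (not the number of scannable offsets), giving a
#' slightly conservative per-bp frequency.
#'
#' @param sequences Character vector of DNA sequences.
#' @inheritParams hit_positions
#' @return One-row tibble: `n_hits`, `total_bp`, `strands`.
#' @export
count_hits <- function(sequences, pattern = "WRGCCCA",
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  pat <- compile_pattern(pattern)
  n_hits <- sum(map_int(sequences, function(s) {
    nrow(hit_positions(s, pat, strands))
  }))
  tibble(n_hits = as.integer(n_hits),
         total_bp = sum(nchar(sequences)),
         strands = strands)
}

#' Expected per-bp motif frequency under a composition null
#'
#' Under the zero-order null (independent bases at the given GC content),
#' the chance that a fixed offset matches the pattern is the product over
#' positions of the summed probabilities of the allowed bases. Both-strand
#' mode adds the reverse-complement pattern's probability (equal for
#' reverse-complement-symmetric base multisets such as `WRGCCCA`).
#'
#' @param pattern IUPAC string or [compile_pattern()] object.
#' @param composition A [composition_model()].
#' @param strands `"both"` (default) or `"forward"`.
#' @return Probability per bp (numeric scalar).
#' @export
expected_frequency <- function(pattern = "WRGCCCA",
                               composition = composition_model(),
                               strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(composition, "composition_model"))
  pat <- compile_pattern(pattern)
  p <- as.numeric(composition)
  names(p) <- names(unclass(composition))
  set_prob <- function(sets) prod(map_dbl(sets, function(b) sum(p[b])))
  out <- set_prob(pat$sets)
  if (strands == "both") out <- out + set_prob(pat$rc_sets)
  out
}

#' Extract peak sequences from a genome
#'
#' @param peaks Peak tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of forward-strand peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  peaks <- validate_intervals(peaks, what = "peak")
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    abort(paste("chromosome(s) absent from genome:",
                paste(missing, collapse = ", ")))
  }
  if (any(peaks$end > nchar(genome[peaks$chrom]))) {
    abort("peak extends past the end of its chromosome")
  }
  substring(genome[peaks$chrom], peaks$start, peaks$end)
}

#' Consensus-motif frequency report
#'
#' Assembles the observed per-bp frequency of a degenerate consensus in a
#' set of sequences, its expected frequency under the zero-order
#' GC-composition null, and their ratio (fold difference over chance).
#'
#' @param sequences Character vector of (peak) sequences.
#' @inheritParams expected_frequency
#' @return A `motif_stats` one-row tibble: `pattern`, `strands`, `n_hits`,
#'   `total_bp`, `observed_freq`, `expected_freq`, `fold`.
#' @export
motif_report <- function(sequences, pattern = "WRGCCCA",
                         composition = composition_model(),
                         strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (length(sequences) == 0) abort("no sequences to scan")
  pat <- compile_pattern(pattern)
  counts <- count_hits(sequences, pat, strands)
  expected <- expected_frequency(pat, composition, strands)
  observed <- counts$n_hits / counts$total_bp
  fold <- if (expected > 0) observed / expected else {
    warn("expected frequency is zero; fold undefined")
    NA_real_
  }
  out <- tibble(pattern = pat$iupac, strands = strands,
                n_hits = counts$n_hits, total_bp = counts$total_bp,
                observed_freq = observed, expected_freq = expected,
                fold = fold)
  structure(out, class = c("motif_stats", class(out)))
}
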