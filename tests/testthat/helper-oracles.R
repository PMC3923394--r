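# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# overlap by explicit position-set intersection
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end))) > 0
}

# window counts by checking every interval against every window
oracle_window_counts <- function(intervals, chrom, clen, w) {
  n_win <- ceiling(clen / w)
  counts <- integer(n_win)
  for (k in seq_len(n_win)) {
    ws <- (k - 1) * w + 1
    we <- min(k * w, clen)
    for (i in seq_len(nrow(intervals))) {
      if (intervals$chrom[i] == chrom &&
          intervals$start[i] <= we && intervals$end[i] >= ws) {
        counts[k] <- counts[k] + 1L
      }
    }
  }
  counts
}

# expand an IUPAC pattern into all concrete words
iupac_tab <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

oracle_expand <- function(iupac) {
  sets <- iupac_tab[strsplit(iupac, "")[[1]]]
  words <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(words[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# count hits by testing every offset against the expansion word set
oracle_motif_count <- function(seq, iupac, both = TRUE) {
  words <- oracle_expand(iupac)
  if (both) words <- c(words, vapply(words, oracle_revcomp, ""))
  m <- nchar(iupac)
  n <- nchar(seq)
  if (n < m) return(0L)
  subs <- substring(seq, 1:(n - m + 1), m:n)
  sum(vapply(words, function(w) sum(subs == w), 0))
}

# hypergeometric upper tail by direct enumeration of tail terms
oracle_hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Poisson upper tail by explicit term summation
oracle_pois_tail <- function(k, lambda, terms = 2000) {
  sum(dpois(k:(k + terms), lambda))
}

# random sequence at given gc
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force zone classification: test the anchor against every zone row
oracle_classify <- function(anchor, chrom, regions) {
  hits <- regions[regions$chrom == chrom &
                    regions$start <= anchor & regions$end >= anchor, ]
  if (nrow(hits) == 0) return(list(zone = "intergenic", gene_id = NA))
  best <- hits[order(abs(hits$tss - anchor), hits$gene_id), ][1, ]
  list(zone = best$zone, gene_id = best$gene_id)
}

fixture_path <- function(f) {
  system.file("extdata", f, package = "chipscape", mustWork = TRUE)
}
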