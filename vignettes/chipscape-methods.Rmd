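---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipscape)
```

chipscape implements the downstream half of a transcription-factor
ChIP-seq analysis: everything after alignment. This vignette records the
statistical models, the coordinate and counting conventions, and the
places where the design was genuinely open and a choice had to be made.

## Coordinate conventions

All internal coordinates are 1-based and fully closed, the GFF3/SAM
convention: the interval `[start, end]` contains both endpoints and has
length `end − start + 1`. This choice is forced by the reference peak
table shipped in `inst/extdata/asr1_top_peaks.tsv`, whose printed lengths
equal `end − start + 1` for every row. BED files are 0-based half-open on
disk and are converted exactly at the file boundary, in both directions.
The midpoint of an even-length interval floors toward `start` — a
deterministic, documented tie-break. Chromosome names are matched by
exact string equality; there is no `chr` aliasing, to avoid silent
mis-joins between files using different naming schemes.

## Read extension and window coverage

Single-end ChIP reads sequence one end of a sonicated fragment, so a
~51 nt read is a biased proxy for a ~400 bp fragment. `extend_reads()`
restores the fragment extent strand-awarely: forward reads keep their
start, reverse reads keep their end, and the other boundary moves to give
a 400 bp interval, clamped to the chromosome. Reads already at least the
target length pass through unchanged.

`window_coverage()` counts, for each consecutive 150 bp window from
position 1, the number of extended intervals overlapping it. "Falling
within" a window is interpreted as *overlap* counting — one fragment can
increment two adjacent windows — matching the semantics of a coverage
histogram in a genome browser. The brute-force oracle in the test suite
checks exactly this definition.

## The enrichment caller is a stand-in

`call_enriched_regions()` honours the core contract of peak calling —
regions with many ChIP reads *and not* many input reads — with the
simplest defensible model: the ChIP count of a window is tested against
`Poisson(scale · (input + pseudocount))`, where `scale` defaults to the
ChIP/input library-size ratio and the pseudocount (default 1) keeps the
mean finite in input-empty windows. Runs of at least `min_windows`
(default 2) adjacent significant windows (default threshold 1e−5) merge
into one peak. The p-value is computed on the log scale so extreme
windows retain finite scores; the score is `−10·log₁₀(min p)` truncated
to one decimal, a cosmetic convention chosen to resemble the scores of
mainstream callers. There is no fragment-shift model estimation, no
duplicate filtering and no FDR sweep: the scientific contribution this
package packages lies downstream of peak calling, and the caller exists
so the pipeline runs end to end on simulated data.

## Genic zones and single-anchor classification

A gene's genic region runs from 3 kb upstream of the transcription start
site to 1 kb past the transcription end site, strand-aware, and
partitions into **promoter** (upstream 3 kb), **gene body** (TSS..TES,
exons plus introns) and **downstream** (1 kb). Zones clamp at chromosome
ends.

Peaks are classified by a single anchor — the summit when available,
otherwise the midpoint — rather than by overlap extent. This was an open
choice: anchor classification makes the four labels (three zones plus
intergenic) a partition, so reported percentages sum to 100, which is the
behaviour implied by published zone splits that add to exactly 100%. When
an anchor lies in the genic regions of several genes, the gene with the
nearest TSS wins, with remaining ties broken by lexicographic gene id —
deterministic and biologically conventional.

## Metagene averaging

For each zone, `metagene_profile()`:

1. selects genes whose genic-region coverage falls *mainly* (> 50%, the
   `majority_threshold`) in that zone — "mainly" is not quantified in the
   source workflow, so a majority is the natural formalisation, and the
   threshold is exposed;
2. cuts the zone into 100 consecutive segments, the first
   `length mod 100` segments one base longer, counting a read in every
   segment it overlaps (consistent with window counting) and reporting
   segments 5′→3′ in gene orientation;
3. normalizes each gene by its own maximum segment count, so every gene
   tops out at 1 and depth differences between genes cancel (per-gene
   scaling, rather than a global maximum across genes, keeps each gene's
   shape on a common scale; the averaged curve then lives in [0, 1]);
4. averages across genes segment-wise with equal weight per gene
   (coverage-weighted averaging would let a single deep gene dominate the
   curve).

Degenerate inputs are handled explicitly: an all-zero gene is skipped
with a warning rather than producing NaN; zones shorter than 100 bp
produce zero-width segments that never accumulate counts.

## Motif statistics against a composition null

The consensus is the degenerate 7-mer `WRGCCCA` = (A/T)(A/G)GCCCA.
`count_hits()` counts *overlapping* occurrences at every offset, and by
default scans both strands — a transcription factor binds double-stranded
DNA — by additionally matching the reverse-complement pattern `TGGGCYW`
on the forward sequence. `N` bases match nothing but still count in the
scanned length, making the observed frequency conservative.

The null is zero-order: bases independent with
`p(G) = p(C) = gc/2`, `p(A) = p(T) = (1 − gc)/2` at the genome's GC
content (default 0.332). The expected per-offset probability is the
product over positions of the allowed-base probability sums; both-strand
scanning doubles it for this pattern class. For `WRGCCCA` at GC = 0.332
this gives 8.47 × 10⁻⁵ per bp single-stranded and 1.69 × 10⁻⁴ both-stranded.
The reference value of 2.64 × 10⁻⁴ reported for this consensus in the
original tomato analysis is not reproduced by the zero-order product
under either strand convention, and the derivation behind it is not
documented; rather than guess, the implementation computes the product
exactly and exposes both the pattern and the strand mode so any
convention can be evaluated. The simulator and the null agree: on
unplanted sequence the empirical hit frequency matches
`expected_frequency()` within binomial noise, which the test suite
asserts.

## Category over-representation

`enrich_categories()` reproduces the standard table arithmetic: percent
in sample `100·k/n`, percent in genome `100·K/N`, and their ratio as fold
over-representation, reported both exactly and rounded to one decimal.
Significance is the one-sided hypergeometric upper tail
`P(X ≥ k)` — the Fisher over-representation test — computed stably via
`phyper()` and verified against exhaustive enumeration in the tests.
Genes carrying several categories count once per category, the usual bin
semantics of functional annotation tools. Benjamini–Hochberg q-values are
appended but the primary ordering is by raw p, matching how such tables
are conventionally reported.

## What the simulator emulates — and what it does not

`simulate_chip_experiment()` produces the study conditions the validation
suite runs under: a 150 kb single-chromosome genome of i.i.d. bases at
33.2% GC; 20 stranded genes of 1.5–3 kb with 1–5 exons, packed so genic
regions are disjoint (the 150 kb default is the smallest round size that
always fits 20 genes plus their 4 kb of genic padding); 10 planted
consensus sites (5 promoter, 5 gene body, centred in their zones, random
strand); ChIP fragments Poisson-distributed per site
(`enrichment = 50`) with midpoints Gaussian around the site centre
(sd = fragment_length/4 = 100 bp — no fragment-position model is
published, and a Gaussian produces the centred peak shapes expected of
point-source binding); uniform Poisson background at 0.01 fragments/bp;
one 51 nt read per 400 bp fragment from a uniformly chosen end. All
stages are deterministic under a root seed with fixed per-stage offsets.

Real data differ in ways the simulator deliberately omits: mappability
and copy-number artifacts (repetitive elements are a documented source of
false peaks in real genomes), sequencing errors and quality scores, PCR
duplicates, GC bias in library preparation, first-order and higher
sequence dependence, and ChIP efficiency variation between sites. Passing
tests therefore demonstrate the correctness of the computations and the
internal consistency of the pipeline under its own model — not that the
caller or the null would be artifact-free on a real genome.

## Numerical and problem-size choices

Validation problem sizes are chosen as the smallest that make the
statistical assertions sharp: 1 Mb for GC and motif-null checks (3
binomial standard deviations on 1 Mb is ±0.14 percentage points of GC);
200 random 5 kb sequences for scan/oracle equivalence; exhaustive
enumeration up to N = 12 for the hypergeometric; and the 150 kb / 20-gene
simulation for end-to-end recovery. Profile flatness under uniform
planting is assessed with a Kolmogorov–Smirnov statistic at α = 0.01 on
the planted positions and on the averaged curve's cumulative mass.

## Known limitations

* Single-chromosome simulation; multi-chromosome inputs are supported in
  analysis but not generated.
* The caller reports no FDR and is not calibrated for broad or weak
  peaks.
* Metagene selection needs at least one qualifying gene per zone; sparse
  runs can legitimately yield no profile for a zone (the pipeline records
  `NULL` rather than failing).
* The motif null is zero-order; a Markov background would be needed for
  dinucleotide-biased genomes.
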