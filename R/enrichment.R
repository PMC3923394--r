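#' Fold over-representation from percentage pairs
#'
#' The ratio of a category's percentage in the target gene set to its
#' percentage in the whole genome. The exact ratio is returned; reports
#' round it to one decimal.
#'
#' @param pct_sample Percent of the target set in the category.
#' @param pct_genome Percent of the genome in the category (> 0).
#' @return Numeric vector of fold ratios (`NA` with a warning where
#'   `pct_genome` is 0).
#' @examples
#' round(fold_enrichment(1.84, 0.12), 1)  # 15.3
#' @export
fold_enrichment <- function(pct_sample, pct_genome) {
  out <- ifelse(pct_genome > 0, pct_sample / pct_genome, NA_real_)
  if (anyNA(out)) warn("pct_genome of 0: fold undefined, returned NA")
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' without replacement from a genome of `N` genes of which `K` belong to
#' the category, the chance of seeing `k` or more category genes. This is
#' the one-sided Fisher over-representation p-value, evaluated stably in
#' log space.
#'
#' @param k Observed category genes in the target set.
#' @param n Target-set size.
#' @param K Category genes in the genome.
#' @param N Genome size (annotated genes).
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1 || length(n) == 1 || length(k) == length(n))
  if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    abort("infeasible counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a gene-to-category mapping table
#'
#' Two-column TSV: `gene_id<TAB>category`, one row per membership (genes
#' may appear under several categories).
#'
#' @param path TSV path (header optional; columns taken positionally when
#'   headers differ).
#' @return Tibble with columns `gene_id`, `category`.
#' @export
read_category_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    if (ncol(df) < 2) abort("category table needs two columns")
    names(df)[1:2] <- c("gene_id", "category")
  }
  distinct(select(df, "gene_id", "category"))
}

#' Functional-category over-representation of target genes
#'
#' For each category with at least one target gene, reports the count in
#' the target set (`k`), the count in the genome (`K`), the percentages
#' `100 k/n` and `100 K/N`, their fold ratio, and the hypergeometric
#' upper-tail p-value, plus Benjamini-Hochberg q-values. Genes carrying
#' several categories count once per category. Target genes absent from
#' the mapping are dropped with a warning (they still count toward `n`
#' only if `count_unannotated = TRUE`; default drops them from `n` too).
#'
#' @param target_genes Character vector of target gene ids.
#' @param categories Mapping tibble (`gene_id`, `category`), e.g. from
#'   [read_category_table()].
#' @param genome_size Total number of annotated genes `N` in the genome.
#' @param count_unannotated Keep unmapped target genes in the target-set
#'   size `n`.
#' @return Tibble sorted by p-value: `category`, `k`, `n`, `K`, `N`,
#'   `pct_sample`, `pct_genome`, `fold`, `fold_rounded`, `p_value`,
#'   `q_value`.
#' @export
enrich_categories <- function(target_genes, categories, genome_size,
                              count_unannotated = FALSE) {
  target_genes <- unique(target_genes)
  if (length(target_genes) == 0) abort("empty target gene set")
  categories <- distinct(categories[, c("gene_id", "category")])
  if (genome_size < length(unique(categories$gene_id))) {
    abort("genome_size smaller than the number of annotated genes")
  }
  known <- target_genes %in% categories$gene_id
  if (any(!known)) {
    warn(sprintf("%d target gene(s) absent from the category table",
                 sum(!known)))
  }
  n <- if (count_unannotated) length(target_genes) else sum(known)
  if (n == 0) abort("no target genes present in the category table")
  in_target <- categories |>
    filter(.data$gene_id %in% target_genes) |>
    group_by(.data$category) |>
    summarise(k = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  genome_counts <- categories |>
    group_by(.data$category) |>
    summarise(K = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  out <- in_target |>
    left_join(genome_counts, by = "category") |>
    mutate(n = n, N = as.integer(genome_size),
           pct_sample = 100 * .data$k / .data$n,
           pct_genome = 100 * .data$K / .data$N,
           fold = fold_enrichment(.data$pct_sample, .data$pct_genome),
           fold_rounded = round(.data$fold, 1),
           p_value = hypergeometric_upper_tail(.data$k, .data$n[1],
                                               .data$K, genome_size)) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$category) |>
    select("category", "k", "n", "K", "N", "pct_sample", "pct_genome",
           "fold", "fold_rounded", "p_value", "q_value")
  out
}
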