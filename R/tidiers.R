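#' Tidy a metagene profile
#'
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @return Tibble: `zone`, `segment`, `value`, `n_genes`.
#' @method tidy metagene_profile
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble(zone = attr(x, "zone"),
         segment = x$segment,
         value = x$value,
         n_genes = attr(x, "n_genes"))
}

#' Tidy motif statistics
#'
#' @param x A `motif_stats` object.
#' @param ... Unused.
#' @return One-row tibble with the motif report fields.
#' @method tidy motif_stats
#' @export
tidy.motif_stats <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a pipeline run: one row per annotated peak
#'
#' @param x A `chipscape_run`.
#' @param ... Unused.
#' @return The peak annotation tibble.
#' @method tidy chipscape_run
#' @export
tidy.chipscape_run <- function(x, ...) {
  as_tibble(x$annotations)
}

#' One-row summary of a pipeline run
#'
#' @param x A `chipscape_run`.
#' @param ... Unused.
#' @return One-row tibble: read/peak counts, genic fraction, zone split,
#'   motif observed/expected frequencies and fold.
#' @method glance chipscape_run
#' @export
glance.chipscape_run <- function(x, ...) {
  d <- x$distribution
  tibble(
    n_chip_reads = nrow(x$chip_reads),
    n_input_reads = nrow(x$input_reads),
    n_peaks = nrow(x$peaks),
    n_genes = nrow(x$genes),
    fraction_genic = if (!is.null(d)) d$fraction_genic else NA_real_,
    pct_promoter = if (!is.null(d)) d$pct_promoter else NA_real_,
    pct_gene_body = if (!is.null(d)) d$pct_gene_body else NA_real_,
    pct_downstream = if (!is.null(d)) d$pct_downstream else NA_real_,
    motif_observed_freq = if (!is.null(x$motif)) x$motif$observed_freq else NA_real_,
    motif_expected_freq = if (!is.null(x$motif)) x$motif$expected_freq else NA_real_,
    motif_fold = if (!is.null(x$motif)) x$motif$fold else NA_real_)
}
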