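# Bundled example score sets from a 76-species vertebrate mitochondrial
# proteome analysis (13 concatenated gene families per species; 10-species
# avian positive-control group). Stored as per-cluster cLtlf values so the
# summary statistics and the Finalize ranking can be recomputed exactly.

#' Bundled per-cluster cLtlf example sets
#'
#' `example_finalize_cltlf()` returns the per-configuration cLtlf score
#' sets used to illustrate the Finalize ranking: one row per cluster, with
#' the configuration label (cluster count), the SVD rank and whether the
#' configuration isolated the avian positive-control group.
#' `example_rank_comparison_cltlf()` returns the per-cluster scores of the
#' ASAP and k-means partitions at ranks 9 and 60 used by the
#' rank-comparison harness example.
#'
#' @return a data.frame (long format, one row per cluster).
#' @export
example_finalize_cltlf <- function() {
  utils::read.delim(system.file("extdata", "mito76_finalize_cltlf.tsv",
                                package = "svdtax", mustWork = TRUE))
}

#' @rdname example_finalize_cltlf
#' @export
example_rank_comparison_cltlf <- function() {
  utils::read.delim(system.file("extdata", "mito76_rank_comparison_cltlf.tsv",
                                package = "svdtax", mustWork = TRUE))
}

#' Finalize-style ranking of bundled example configurations
#'
#' Applies the median-cLtlf Finalize ordering to the bundled example
#' score sets, excluding configurations that failed to isolate the
#' positive control.
#'
#' @return data.frame: config, rank_k, plus [cltlf_stats()] columns,
#'   sorted by descending median.
#' @export
example_finalize_ranking <- function() {
  df <- example_finalize_cltlf()
  df <- df[df$isolates_control, ]
  groups <- split(df, list(df$config, df$rank_k), drop = TRUE)
  rows <- lapply(groups, function(g) {
    st <- cltlf_stats(g$cltlf)
    data.frame(config = g$config[[1]], rank_k = g$rank_k[[1]],
               n_clusters = st$n_clusters, min = st$min, max = st$max,
               mean = st$mean, sum = st$sum, sd = st$sd, lcq = st$lcq,
               median = st$median)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median, out$rank_k), ]
  rownames(out) <- NULL
  out
}
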