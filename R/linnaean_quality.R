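# Scoring partitions against Linnaean taxonomy. A cluster's cLtlf
# ("common Linnaean taxonomy level frequency") is its size times the number
# of lineage ranks shared by all its members; partition-level statistics
# (sum, mean, sample sd, Lcq = sum/sd, median) summarize a clustering.

#' Number of Linnaean levels shared by a set of lineages
#'
#' The length of the longest common prefix of the lineages in rank order
#' (Superregnum -> Species). Distinct species share at most the genus, so
#' the value is capped at 13; a singleton scores 13 by the same convention.
#'
#' @param lineages list of character(14) lineages.
#' @return integer in `[1, 13]` (0 only if lineages disagree at rank 1).
#' @export
shared_levels <- function(lineages) {
  if (length(lineages) == 0L) stop("no lineages given")
  if (length(lineages) == 1L) return(MAX_SHARED_LEVELS)
  depth <- 0L
  for (r in seq_len(N_LINNAEAN_RANKS)) {
    taxa <- vapply(lineages, `[[`, character(1), r)
    if (length(unique(taxa)) > 1L) break
    depth <- r
  }
  min(depth, MAX_SHARED_LEVELS)
}

#' cLtlf of one cluster
#'
#' Cluster size times the number of Linnaean levels its members share.
#' A singleton scores 1 x 13 = 13, the minimum for a species with a
#' complete lineage sharing at least the root rank with itself.
#'
#' @param cluster character vector of species ids.
#' @param taxonomy named lineage list ([read_taxonomy()]) or a
#'   `species_dataset` with lineages attached.
#' @return integer cLtlf score.
#' @export
cltlf <- function(cluster, taxonomy) {
  lineages <- lookup_lineages(cluster, taxonomy)
  length(cluster) * shared_levels(lineages)
}

lookup_lineages <- function(ids, taxonomy) {
  if (inherits(taxonomy, "species_dataset")) {
    taxonomy <- lapply(taxonomy$records, `[[`, "lineage")
  }
  lapply(ids, function(id) {
    lin <- taxonomy[[id]]
    if (is.null(lin)) stop("no lineage for species '", id, "'")
    lin
  })
}

#' Summary statistics of a set of per-cluster cLtlf values
#'
#' The standard deviation uses the sample (n - 1) denominator; the median
#' of an even count is the mean of the two central order statistics;
#' Lcq = sum / sd is `NA` when the sd is zero or undefined.
#'
#' @param values numeric vector of per-cluster cLtlf scores.
#' @return list with `n_clusters`, `min`, `max`, `mean`, `sum`, `sd`,
#'   `lcq`, `median`.
#' @export
cltlf_stats <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  s <- if (length(values) > 1L) stats::sd(values) else NA_real_
  list(
    n_clusters = length(values),
    min = min(values), max = max(values),
    mean = mean(values), sum = sum(values),
    sd = s,
    lcq = if (!is.na(s) && s > 0) sum(values) / s else NA_real_,
    median = stats::median(values)
  )
}

#' Quality report of a partition against a taxonomy
#'
#' @param partition an `asap_partition` (or plain list of id vectors).
#' @param taxonomy named lineage list or lineage-bearing
#'   `species_dataset`.
#' @return a `quality_report`: `per_cluster` data.frame (cluster,
#'   n_species, shared_levels, cltlf) plus the [cltlf_stats()] fields.
#' @export
quality_report <- function(partition, taxonomy) {
  clusters <- partition_clusters(partition)
  if (length(clusters) == 0L) stop("empty partition")
  per <- data.frame(
    cluster = seq_along(clusters),
    n_species = lengths(clusters),
    shared_levels = vapply(clusters, function(cl) {
      shared_levels(lookup_lineages(cl, taxonomy))
    }, integer(1))
  )
  per$cltlf <- per$n_species * per$shared_levels
  structure(c(list(per_cluster = per), cltlf_stats(per$cltlf)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "quality_report: %d clusters | sum cLtlf %d | mean %.2f | sd %.2f | Lcq %s | median %.2f\n",
    x$n_clusters, x$sum, x$mean,
    if (is.na(x$sd)) NA else x$sd,
    if (is.na(x$lcq)) "undefined" else sprintf("%.2f", x$lcq),
    x$median))
  invisible(x)
}

#' Export a quality report as a Table-shaped TSV row set
#'
#' @param report a `quality_report`.
#' @param rank_k rank used to build the partition (for the `rank` column).
#' @param label row label (e.g. "08clusters").
#' @param path optional output TSV.
#' @return one-row data.frame: label, rank, N, min, max, mean, sum, sd,
#'   lcq, median.
#' @export
quality_row <- function(report, rank_k = NA, label = "", path = NULL) {
  df <- data.frame(
    label = label, rank = rank_k, N = report$n_clusters,
    min_cltlf = report$min, max_cltlf = report$max,
    mean_cltlf = report$mean, sum_cltlf = report$sum,
    sd_cltlf = report$sd, lcq = report$lcq, median_cltlf = report$median
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}

#' Does a partition isolate a control group?
#'
#' A control group is isolated when some cluster equals it exactly
#' ("integrally and isolatedly"). Otherwise the cluster holding the most
#' control species is characterized: its cLtlf, how many foreign species it
#' contains, and how many control species sit elsewhere.
#'
#' @param partition an `asap_partition` or list of id vectors.
#' @param control character vector of control species ids.
#' @param taxonomy optional taxonomy for the reported cLtlf (`NA` without).
#' @return list: `isolated`, `control_cluster_cltlf`, `n_foreign`,
#'   `n_missing`.
#' @export
control_isolation <- function(partition, control, taxonomy = NULL) {
  if (length(control) == 0L) stop("control set is empty")
  clusters <- partition_clusters(partition)
  hits <- vapply(clusters, function(cl) sum(cl %in% control), integer(1))
  best <- which.max(hits)
  cl <- clusters[[best]]
  isolated <- setequal(cl, control)
  list(
    isolated = isolated,
    control_cluster_cltlf = if (!is.null(taxonomy)) cltlf(cl, taxonomy)
                            else NA_integer_,
    n_foreign = sum(!(cl %in% control)),
    n_missing = sum(!(control %in% cl))
  )
}
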