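# ASAP ("As Simple As Possible") threshold agglomerative clustering.
# Take a pivot, absorb every remaining species strictly closer than d,
# remove them, repeat. Unlike single linkage, merged clusters are never
# re-inserted into the distance matrix.

#' ASAP threshold clustering of a distance matrix
#'
#' Iteratively takes the first remaining species in pivot order as the
#' pivot; its cluster is the pivot plus all remaining species at distance
#' strictly less than `d`; those are removed and the process repeats.
#' With `d = 0` every species is a singleton; with `d` above the maximum
#' pairwise distance a single cluster holds everything.
#'
#' @param matrix a `species_dist` (symmetric, zero diagonal, labelled).
#' @param d non-negative distance threshold.
#' @param pivot_order `"fixed"` (alphabetical species order, fully
#'   deterministic) or an integer seed for a random pivot order.
#' @return an `asap_partition`: list with `clusters` (list of species-id
#'   vectors) and `provenance` (k_used, d, c, pivot_order).
#' @export
asap_cluster <- function(matrix, d, pivot_order = "fixed") {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0)
  m <- as.matrix(matrix)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  order_ids <- pivot_sequence(ids, pivot_order)
  remaining <- order_ids
  clusters <- list()
  while (length(remaining) > 0L) {
    pivot <- remaining[[1L]]
    near <- remaining[m[pivot, remaining] < d]
    cluster <- unique(c(pivot, near))
    clusters[[length(clusters) + 1L]] <- cluster
    remaining <- setdiff(remaining, cluster)
  }
  new_partition(clusters, provenance = list(
    k_used = attr(matrix, "k_used"), d = d, c = length(clusters),
    pivot_order = pivot_order))
}

pivot_sequence <- function(ids, pivot_order) {
  if (identical(pivot_order, "fixed")) {
    sort(ids)
  } else if (is.numeric(pivot_order) && length(pivot_order) == 1L) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old))
    set.seed(as.integer(pivot_order))
    sample(ids)
  } else {
    stop("pivot_order must be \"fixed\" or an integer seed")
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

new_partition <- function(clusters, provenance = list()) {
  clusters <- lapply(clusters, as.character)
  if (any(lengths(clusters) == 0L)) stop("empty cluster in partition")
  structure(list(clusters = clusters, provenance = provenance),
            class = "asap_partition")
}

#' @export
print.asap_partition <- function(x, ...) {
  p <- x$provenance
  cat("asap_partition:", length(x$clusters), "clusters over",
      length(unlist(x$clusters)), "species")
  if (!is.null(p$d)) cat(sprintf(" (d = %.4g)", p$d))
  if (!is.null(p$k_used)) cat(sprintf(", k = %d", p$k_used))
  cat("\n")
  invisible(x)
}

#' Cluster count as a step function of the ASAP threshold
#'
#' ASAP's decisions depend only on comparisons of distances with `d`, so
#' the cluster count is constant between consecutive distinct pairwise
#' distances. Evaluating at 0, at the midpoints between consecutive sorted
#' unique distances, and just above the maximum therefore enumerates every
#' achievable count.
#'
#' @param matrix a `species_dist`.
#' @param pivot_order as in [asap_cluster()].
#' @return data.frame with columns `threshold`, `n_clusters`, `lo`, `hi`
#'   (the interval of thresholds each row represents), sorted by
#'   threshold.
#' @export
cluster_count_profile <- function(matrix, pivot_order = "fixed") {
  m <- as.matrix(matrix)
  vals <- sort(unique(m[upper.tri(m)]))
  vals <- vals[vals > 0]
  if (length(vals) == 0L) {
    grid <- 0
    lo <- 0
    hi <- Inf
  } else {
    mids <- if (length(vals) > 1L) (vals[-1L] + vals[-length(vals)]) / 2
            else numeric(0)
    eps <- max(vals) * 1e-6 + 1e-12
    grid <- c(0, mids, max(vals) + eps)
    lo <- c(0, vals)
    hi <- c(vals, Inf)
  }
  parts <- lapply(grid, function(d) asap_cluster(matrix, d, pivot_order))
  counts <- vapply(parts, function(p) length(p$clusters), integer(1))
  keys <- vapply(parts, partition_key, character(1))
  data.frame(threshold = grid, n_clusters = counts, lo = lo, hi = hi,
             partition_key = keys)
}

# canonical fingerprint of a partition (order-independent)
partition_key <- function(partition) {
  cl <- vapply(partition_clusters(partition), function(x) {
    paste(sort(x), collapse = ",")
  }, character(1))
  paste(sort(cl), collapse = ";")
}

#' Representative threshold at which ASAP yields exactly c clusters
#'
#' The partition (hence the cluster count) is piecewise constant in the
#' threshold; a target count may be realized by several distinct
#' partitions, each holding on its own plateau of `d` values. The default
#' `"stable"` rule returns the largest threshold inside the widest such
#' plateau - the partition most robust to perturbation of the distances.
#' `"largest"` returns the largest realizing grid threshold outright.
#'
#' @param profile output of [cluster_count_profile()].
#' @param c target cluster count.
#' @param rule `"stable"` (widest plateau, default) or `"largest"`.
#' @return a threshold achieving exactly `c` clusters, or `NA` when none
#'   does.
#' @export
threshold_for_count <- function(profile, c, rule = c("stable", "largest")) {
  rule <- match.arg(rule)
  hit <- which(profile$n_clusters == c)
  if (length(hit) == 0L) return(NA_real_)
  if (rule == "largest") return(max(profile$threshold[hit]))
  # maximal runs of consecutive profile rows holding the same partition
  same <- c(1L, diff(hit) != 1L |
              profile$partition_key[hit[-1L]] !=
              profile$partition_key[hit[-length(hit)]])
  runs <- split(hit, cumsum(same))
  width <- vapply(runs, function(r) {
    max(profile$hi[r]) - min(profile$lo[r])
  }, numeric(1))
  best <- runs[[which.max(width)]]
  max(profile$threshold[best])
}
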