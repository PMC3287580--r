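# Seeded k-means over latent-space columns plus the rank-comparison
# harness. Clustering itself is delegated to stats::kmeans (Lloyd
# iterations), seeded with c distinct species coordinates so runs are
# reproducible; this module adds the species-space plumbing and the
# taxonomy-scored comparison table.

#' Seeded k-means over a reduced species space
#'
#' Runs Lloyd-style k-means on the species columns of `space`, initialized
#' from `c` distinct species coordinate vectors drawn uniformly at random
#' under `seed`. Duplicate coordinates are collapsed before drawing so the
#' initial centers are always distinct.
#'
#' @param space a `reduced_space` (or plain matrix, columns = species).
#' @param c number of clusters, `1 <= c <=` number of distinct points.
#' @param seed integer seed making the initialization reproducible.
#' @param max_iter,tol Lloyd iteration cap and (centroid-shift) tolerance;
#'   `tol` is accepted for interface stability but Lloyd runs to
#'   assignment convergence within `max_iter`.
#' @return a `kmeans_result`: `assignment` (named integer vector),
#'   `clusters` (list of id vectors), `centroids`, `n_iter`, `inertia`.
#' @export
km_cluster <- function(space, c, seed = 1L, max_iter = 300L, tol = 1e-6) {
  pts <- if (inherits(space, "reduced_space")) t(space$dk) else t(as.matrix(space))
  n <- nrow(pts)
  c <- as.integer(c)
  if (c < 1L || c > n) stop("c must be in [1, ", n, "]")
  uniq <- !duplicated(round(pts, 12L))
  if (c > sum(uniq)) {
    stop("c = ", c, " exceeds the ", sum(uniq), " distinct points")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(as.integer(seed))
  centers <- pts[sample(which(uniq), c), , drop = FALSE]
  km <- suppressWarnings(
    stats::kmeans(pts, centers = centers, iter.max = max_iter,
                  algorithm = "Lloyd"))
  assignment <- stats::setNames(km$cluster, rownames(pts))
  structure(
    list(assignment = assignment,
         clusters = unname(split(names(assignment), assignment)),
         centroids = km$centers, n_iter = km$iter,
         inertia = km$tot.withinss),
    class = "kmeans_result"
  )
}

#' Import an externally produced clustering assignment
#'
#' Reads a TSV with columns `species_id` and `cluster` (header required),
#' e.g. from a third-party clusterer, so it can be scored by
#' [quality_report()] alongside the built-in algorithms.
#'
#' @param path TSV path.
#' @return an `asap_partition`-compatible partition object.
#' @export
read_assignment <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "cluster") %in% names(df))) {
    stop("assignment file needs columns species_id and cluster")
  }
  new_partition(unname(split(df$species_id, df$cluster)),
                provenance = list(source = path))
}

#' Compare ASAP and k-means across two SVD ranks
#'
#' Reproduces the reduced-rank versus full-rank comparison: both
#' algorithms are run at the same cluster count `c` on a truncated space
#' and on the full-rank space, each partition is scored against the
#' taxonomy, and the Linnaean-cluster-quality gain
#' `100 * (Lcq_reduced / Lcq_full - 1)` is reported per algorithm.
#'
#' @param space_k truncated `reduced_space`.
#' @param space_full full-rank `reduced_space` over the same species.
#' @param c target cluster count.
#' @param taxonomy lineage source for [quality_report()].
#' @param seed seed for [km_cluster()].
#' @param pivot_order passed to [asap_cluster()].
#' @return a data.frame with one row per (algorithm, rank): label, rank,
#'   N, min/max/mean/sum/sd cLtlf, Lcq, median, and `lcq_gain_pct` on the
#'   reduced-rank rows. ASAP rows are absent when no threshold realizes
#'   `c` (`NA` row retained with a note).
#' @export
compare_algorithms <- function(space_k, space_full, c, taxonomy, seed = 1L,
                               pivot_order = "fixed") {
  stopifnot(identical(space_k$species_order, space_full$species_order))
  run_one <- function(space, algorithm) {
    if (algorithm == "asap") {
      dm <- species_distances(space)
      d <- threshold_for_count(cluster_count_profile(dm, pivot_order), c)
      if (is.na(d)) return(NULL)
      part <- asap_cluster(dm, d, pivot_order)
    } else {
      part <- new_partition(km_cluster(space, c, seed = seed)$clusters)
    }
    quality_report(part, taxonomy)
  }
  rows <- list()
  for (algorithm in c("kmeans", "asap")) {
    rep_k <- run_one(space_k, algorithm)
    rep_f <- run_one(space_full, algorithm)
    for (spec in list(list(r = rep_k, rank = space_k$k, which = "reduced"),
                      list(r = rep_f, rank = space_full$k, which = "full"))) {
      if (is.null(spec$r)) next
      row <- quality_row(spec$r, rank_k = spec$rank, label = algorithm)
      row$lcq_gain_pct <-
        if (spec$which == "reduced" && !is.null(rep_f) &&
            !is.na(rep_f$lcq) && rep_f$lcq > 0 && !is.na(rep_k$lcq)) {
          100 * (rep_k$lcq / rep_f$lcq - 1)
        } else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
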