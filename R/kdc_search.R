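# The recursive kdcSearch driver. Sweeps SVD rank k, derives the distance
# thresholds d that realize target cluster counts c, scores every (k, d, c)
# triad against the taxonomy, gates on positive-control isolation, recurses
# on the retained species subset when no triad isolates the control, and
# ranks the isolating triads by median per-cluster cLtlf ("Finalize").

#' Configuration for the kdc parameter search
#'
#' EDRD (Empirical Dimensional Range Division) is the grid step used for
#' both the rank sweep and the target cluster counts: `max(1, round(n/25))`
#' (step 3 for 76 species). Ranks default to `seq(3, n, by = edrd)`,
#' target counts to `seq(edrd, n - 1, by = edrd)`.
#'
#' @param n number of species.
#' @param control character vector: positive-control species ids.
#' @param secondary_control optional second control set.
#' @param ranks ranks k to try (default EDRD grid from 3 to n).
#' @param cluster_counts target cluster counts c (default EDRD multiples
#'   below n).
#' @param edrd grid step override.
#' @param max_recursions recursion-depth cap (the published analysis
#'   terminated at depth 1; the cap guarantees termination).
#' @param pivot_order passed to [asap_cluster()].
#' @return a `kdc_config` list.
#' @export
kdc_config <- function(n, control, secondary_control = NULL, ranks = NULL,
                       cluster_counts = NULL, edrd = NULL,
                       max_recursions = 3L, pivot_order = "fixed") {
  n <- as.integer(n)
  if (is.null(edrd)) edrd <- max(1L, as.integer(round(n / 25)))
  if (is.null(ranks)) ranks <- seq.int(min(3L, n), n, by = edrd)
  if (is.null(cluster_counts)) {
    cluster_counts <- seq.int(edrd, max(edrd, n - 1L), by = edrd)
  }
  stopifnot(all(ranks >= 1L), all(ranks <= n),
            all(cluster_counts >= 1L), all(cluster_counts <= n))
  structure(
    list(n = n, control = control, secondary_control = secondary_control,
         ranks = as.integer(ranks),
         cluster_counts = as.integer(cluster_counts),
         edrd = as.integer(edrd), max_recursions = as.integer(max_recursions),
         pivot_order = pivot_order),
    class = "kdc_config"
  )
}

#' Sweep (k, d, c) triads over one dataset
#'
#' For each rank k the species are projected into the rank-k latent space,
#' the distance matrix and its cluster-count profile are built, and for each
#' target count c the largest threshold d realizing exactly c clusters (if
#' any) yields a scored result. Requested counts no threshold achieves are
#' silently absent.
#'
#' @param A a `trigram_matrix` (columns restricted to the current species
#'   subset).
#' @param taxonomy named lineage list or lineage-bearing `species_dataset`.
#' @param config a `kdc_config`.
#' @param factors optional precomputed [svd_decompose()] result for `A`.
#' @return list of `kdc_result`s, each with `k`, `d`, `c`, `partition`,
#'   `report`, `control_isolated`, `secondary_isolated`, `n_singletons`.
#' @export
kdc_sweep <- function(A, taxonomy, config, factors = NULL) {
  if (is.null(factors)) factors <- svd_decompose(A)
  ranks <- config$ranks[config$ranks <= factors$rank]
  results <- list()
  for (k in ranks) {
    dm <- species_distances(svd_reduce(factors, k))
    profile <- cluster_count_profile(dm, config$pivot_order)
    for (cc in config$cluster_counts) {
      d <- threshold_for_count(profile, cc)
      if (is.na(d)) next
      part <- asap_cluster(dm, d, config$pivot_order)
      results[[length(results) + 1L]] <-
        score_kdc(part, k, d, taxonomy, config)
    }
  }
  results
}

score_kdc <- function(partition, k, d, taxonomy, config) {
  report <- quality_report(partition, taxonomy)
  iso <- control_isolation(partition, config$control, taxonomy)
  sec <- if (!is.null(config$secondary_control)) {
    control_isolation(partition, config$secondary_control, taxonomy)$isolated
  } else NA
  structure(
    list(k = k, d = d, c = length(partition$clusters),
         partition = partition, report = report,
         control_isolated = iso$isolated,
         control_cluster_cltlf = iso$control_cluster_cltlf,
         secondary_isolated = sec,
         n_singletons = sum(lengths(partition$clusters) == 1L)),
    class = "kdc_result"
  )
}

#' @export
print.kdc_result <- function(x, ...) {
  cat(sprintf(
    "kdc_result: k=%d d=%.4g c=%d | median cLtlf %.2f | control %s\n",
    x$k, x$d, x$c, x$report$median,
    if (x$control_isolated) "isolated" else "not isolated"))
  invisible(x)
}

#' Select the species to retain for the next recursion
#'
#' When no triad isolates the control, the best available result (largest
#' control-cluster cLtlf, ties broken by fewest singleton clusters) is
#' chosen and every species sitting in a singleton cluster of that
#' partition is dropped: clusters of one element carry no ancestry signal.
#' Positive-control members are never dropped - removing them would make
#' isolation unattainable on every later recursion.
#'
#' @param results non-empty list of `kdc_result`s from [kdc_sweep()].
#' @param config a `kdc_config`.
#' @return list: `retained` (character vector of ids), `best` (the chosen
#'   `kdc_result`).
#' @export
kdc_retain <- function(results, config) {
  if (length(results) == 0L) stop("no kdc results to recurse on")
  score <- vapply(results, `[[`, numeric(1), "control_cluster_cltlf")
  singles <- vapply(results, `[[`, integer(1), "n_singletons")
  ord <- order(-score, singles)
  best <- results[[ord[1L]]]
  clusters <- best$partition$clusters
  retained <- union(unlist(clusters[lengths(clusters) > 1L],
                           use.names = FALSE),
                    config$control)
  if (length(retained) < length(config$control) + 2L) {
    stop("recursion would leave only ", length(retained),
         " species (need at least |control| + 2)")
  }
  list(retained = sort(retained), best = best)
}

#' Rank control-isolating triads by median cLtlf ("Finalize")
#'
#' Sorts descending by the partition's median per-cluster cLtlf;
#' ties are broken by fewer singleton clusters, then by secondary-control
#' isolation, then by larger mean cLtlf, then by smaller rank k. The mean
#' separates equal-median candidates that differ in how much total
#' Linnaean agreement their clusters carry (a partition merging two
#' unrelated groups keeps the median but drags the mean down).
#' Configurations heavy in singleton clusters (each scoring the minimum
#' cLtlf of 13) sink naturally, which is why the median - not Lcq - drives
#' this step.
#'
#' @param results list of `kdc_result`s, every one with
#'   `control_isolated = TRUE`.
#' @return a `kdc_finalize` list: `results` (sorted), `table` (ranking
#'   data.frame: rank_k, d, n_clusters, median and companions).
#' @export
kdc_finalize <- function(results) {
  if (length(results) == 0L) stop("no isolating configuration")
  if (!all(vapply(results, `[[`, logical(1), "control_isolated"))) {
    stop("finalize requires control_isolated results only")
  }
  med <- vapply(results, function(r) r$report$median, numeric(1))
  singles <- vapply(results, `[[`, integer(1), "n_singletons")
  sec <- vapply(results, function(r) isTRUE(r$secondary_isolated), logical(1))
  mn <- vapply(results, function(r) r$report$mean, numeric(1))
  ks <- vapply(results, `[[`, numeric(1), "k")
  ord <- order(-med, singles, -sec, -mn, ks)
  results <- results[ord]
  table <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    cbind(position = i,
          quality_row(r$report, rank_k = r$k,
                      label = sprintf("%02dclusters", r$c)),
          d = r$d, n_singletons = r$n_singletons,
          secondary_isolated = r$secondary_isolated)
  }))
  structure(list(results = results, table = table), class = "kdc_finalize")
}

#' @export
print.kdc_finalize <- function(x, ...) {
  cat("kdc_finalize:", length(x$results), "isolating configuration(s)\n")
  print(utils::head(x$table[, c("position", "label", "rank", "median_cltlf",
                                "n_singletons")], 10L))
  invisible(x)
}

#' Full recursive kdc search over a dataset
#'
#' Runs [kdc_sweep()]; if some triad isolates the positive control the
#' recursion stops and [kdc_finalize()] ranks all isolating triads of that
#' depth. Otherwise singleton-cluster species of the best triad are dropped
#' and the sweep repeats on the remainder, up to `max_recursions` times.
#'
#' @param dataset a lineage-bearing `species_dataset` whose
#'   `positive_control` is non-empty (or pass `config` explicitly).
#' @param config optional `kdc_config`; defaults are derived from the
#'   dataset.
#' @param normalize passed to [build_trigram_matrix()].
#' @return a `kdc_search` list: `finalize` (ranked isolating triads, or
#'   NULL if none found), `depth` (recursions executed), `trace`
#'   (per-depth summary data.frame), `retained` (ids used at the final
#'   depth), `config`.
#' @export
kdc_search <- function(dataset, config = NULL, normalize = FALSE) {
  if (is.null(config)) {
    config <- kdc_config(length(dataset$records), dataset$positive_control,
                         dataset$secondary_control)
  }
  if (length(config$control) == 0L) stop("a positive-control set is required")
  A_full <- build_trigram_matrix(dataset, normalize = normalize)
  ids <- colnames(A_full)
  trace <- list()
  depth <- 0L
  repeat {
    A <- A_full[, ids, drop = FALSE]
    cfg <- kdc_config(length(ids), config$control, config$secondary_control,
                      edrd = config$edrd,
                      max_recursions = config$max_recursions,
                      pivot_order = config$pivot_order)
    results <- kdc_sweep(A, dataset, cfg)
    isolating <- Filter(function(r) r$control_isolated, results)
    trace[[depth + 1L]] <- data.frame(
      depth = depth, n_species = length(ids), n_results = length(results),
      n_isolating = length(isolating))
    if (length(isolating) > 0L || depth >= config$max_recursions ||
        length(results) == 0L) {
      fin <- if (length(isolating) > 0L) kdc_finalize(isolating) else NULL
      return(structure(
        list(finalize = fin, depth = depth,
             trace = do.call(rbind, trace), retained = ids, config = config),
        class = "kdc_search"))
    }
    sel <- kdc_retain(results, cfg)
    ids <- sel$retained
    depth <- depth + 1L
  }
}

#' @export
print.kdc_search <- function(x, ...) {
  cat("kdc_search: depth", x$depth, "|", length(x$retained),
      "species retained |",
      if (is.null(x$finalize)) "control never isolated"
      else paste(length(x$finalize$results), "isolating configuration(s)"),
      "\n")
  invisible(x)
}
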