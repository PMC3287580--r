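# Neighbor-joining cladogram output. Tree construction is delegated to
# ape::nj (classic Saitou-Nei agglomeration); this module adds input
# validation, the NEIGHBOR-style treatment of negative branch-length
# estimates (clamp to zero, shift the deficit onto the sister branch), and
# fixed-precision Newick serialization.

#' Neighbor-joining tree from a species distance matrix
#'
#' @param matrix a `species_dist` (or any symmetric labelled matrix with
#'   zero diagonal), at least 3 taxa, no NaN/NA.
#' @param labels optional replacement tip labels (e.g. mnemonics).
#' @return an unrooted `phylo` tree (ape) with non-negative branch
#'   lengths.
#' @export
nj_tree <- function(matrix, labels = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(m))) stop("distance matrix contains NA/NaN/Inf")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is asymmetric")
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("t", seq_len(nrow(m))),
                        paste0("t", seq_len(nrow(m))))
  }
  tree <- ape::nj(stats::as.dist(m))
  clamp_negative_edges(tree)
}

# NEIGHBOR-style fix-up: a negative estimated branch length is set to zero
# and its (negative) amount added to the sister branch at the same node, so
# path lengths through the pair are preserved.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[[1L]]
    parent <- tree$edge[e, 1L]
    siblings <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(siblings) > 0L) {
      s <- siblings[[1L]]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
      if (tree$edge.length[s] < 0) tree$edge.length[s] <- 0
    }
  }
  tree
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are printed with 6 decimals; the string ends with ";".
#'
#' @param tree a `phylo` object (e.g. from [nj_tree()]).
#' @param path optional output file.
#' @return the Newick string (invisibly when written to `path`).
#' @export
to_newick <- function(tree, path = NULL) {
  txt <- format_newick_lengths(ape::write.tree(tree, digits = 10))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# rewrite every ":<length>" with fixed 6-decimal formatting
format_newick_lengths <- function(txt) {
  m <- gregexpr(":[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", txt)
  regmatches(txt, m) <- lapply(regmatches(txt, m), function(tok) {
    sprintf(":%.6f", as.numeric(sub("^:", "", tok)))
  })
  txt
}
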