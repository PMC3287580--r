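# The latent space: thin SVD of the trigram matrix, rank-k reduction
# D_k = Sigma_k V_k^T, and Euclidean distances between species columns.

#' Thin singular value decomposition of the trigram matrix
#'
#' Factorizes A = U diag(sigma) V^T with sigma non-increasing. Only the thin
#' factors are computed (the trigram dimension is 8000, far above the
#' species count). The numerical rank r counts singular values above
#' 1e-10 * sigma[1].
#'
#' @param A numeric matrix (typically a `trigram_matrix`) with >= 2 columns.
#' @return an `svd_factors` list: `u`, `sigma`, `v`, `rank`,
#'   `species_order`.
#' @export
svd_decompose <- function(A) {
  A <- unclass(A)
  if (ncol(A) < 2L) stop("need at least 2 species columns")
  if (all(A == 0)) stop("degenerate input: all-zero matrix")
  s <- svd(A)
  r <- sum(s$d > 1e-10 * s$d[1])
  structure(
    list(u = s$u, sigma = s$d, v = s$v, rank = r,
         species_order = colnames(A)),
    class = "svd_factors"
  )
}

#' Rank-k reduced species representation
#'
#' Builds the k x n latent coordinate matrix D_k = diag(sigma[1..k]) V_k^T,
#' column j holding species j's k coordinates. Distances computed on D_k at
#' k = rank(A) equal distances on A's raw columns (orthogonal invariance);
#' smaller k discards the low-variance directions treated as noise.
#'
#' @param factors an `svd_factors` object.
#' @param k number of singular values to keep, 1 <= k <= numerical rank.
#' @return a `reduced_space` list: `k`, `dk` (k x n), `species_order`.
#' @export
svd_reduce <- function(factors, k) {
  stopifnot(inherits(factors, "svd_factors"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > factors$rank) {
    stop("k must be an integer in [1, ", factors$rank, "]")
  }
  dk <- diag(factors$sigma[seq_len(k)], nrow = k) %*%
    t(factors$v[, seq_len(k), drop = FALSE])
  colnames(dk) <- factors$species_order
  structure(list(k = k, dk = dk, species_order = factors$species_order),
            class = "reduced_space")
}

#' Euclidean distance matrix between species in a latent space
#'
#' @param space a `reduced_space` (or any matrix whose columns are species).
#' @return a `species_dist`: symmetric n x n matrix with zero diagonal and
#'   attribute `k_used`.
#' @export
species_distances <- function(space) {
  if (inherits(space, "reduced_space")) {
    m <- space$dk
    k <- space$k
  } else {
    m <- as.matrix(space)
    k <- nrow(m)
  }
  d <- as.matrix(stats::dist(t(m)))
  dimnames(d) <- list(colnames(m), colnames(m))
  structure(d, k_used = k, class = c("species_dist", class(d)))
}

#' Export the singular-value spectrum for scree inspection
#'
#' @param factors an `svd_factors` object.
#' @param path optional TSV output path.
#' @return data.frame with columns `index`, `sigma`.
#' @export
sigma_spectrum <- function(factors, path = NULL) {
  df <- data.frame(index = seq_along(factors$sigma), sigma = factors$sigma)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  df
}
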