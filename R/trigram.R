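# Amino-acid trigram feature extraction: every species' concatenated
# protein sequence becomes a count vector over the 8000 trigrams of the
# 20-letter alphabet; the dataset becomes the 8000 x n matrix A.

all_trigrams <- function() {
  g <- expand.grid(c3 = AA_ALPHABET, c2 = AA_ALPHABET, c1 = AA_ALPHABET,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)   # lexicographic over the alphabet
}

#' Trigram count vector of one amino-acid sequence
#'
#' Counts overlapping (stride-1) windows of length 3. A sequence of cleaned
#' length L yields max(0, L - 2) windows, so the vector sums to that.
#'
#' @param sequence amino-acid string over the 20-letter alphabet
#'   (cleaning already applied; see [read_species_fasta()]).
#' @return named integer vector of length 8000, trigrams in lexicographic
#'   order.
#' @export
trigram_vector <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  trigrams <- all_trigrams()
  L <- nchar(sequence)
  counts <- integer(length(trigrams))
  names(counts) <- trigrams
  if (L >= 3L) {
    chars <- strsplit(sequence, "")[[1]]
    bad <- which(!(chars %in% AA_ALPHABET))
    if (length(bad) > 0L) {
      stop("residue '", chars[bad[1]], "' at position ", bad[1],
           " is outside the 20-letter amino-acid alphabet")
    }
    windows <- paste0(chars[1:(L - 2L)], chars[2:(L - 1L)], chars[3:L])
    tab <- tabulate(match(windows, trigrams), nbins = length(trigrams))
    counts[] <- tab
  }
  counts
}

#' Build the trigram count matrix A for a dataset
#'
#' @param dataset a `species_dataset` with at least 2 species.
#' @param normalize if `TRUE`, each column is divided by its sum (L1
#'   relative frequencies). Off by default: raw counts carry the
#'   sequence-length signal the downstream distances use.
#' @return a `trigram_matrix`: 8000 x n numeric matrix, rows named by
#'   trigram, columns by species id in dataset order.
#' @export
build_trigram_matrix <- function(dataset, normalize = FALSE) {
  ids <- names(dataset$records)
  if (length(ids) < 2L) stop("need at least 2 species")
  cols <- vapply(ids, function(id) {
    as.numeric(trigram_vector(dataset$records[[id]]$sequence))
  }, numeric(8000L))
  A <- matrix(cols, nrow = 8000L, dimnames = list(all_trigrams(), ids))
  if (normalize) {
    sums <- colSums(A)
    A <- sweep(A, 2L, ifelse(sums > 0, sums, 1), "/")
  }
  structure(A, class = c("trigram_matrix", class(A)))
}

#' Export a trigram matrix as MatrixMarket coordinate text
#'
#' Writes the non-zero entries in MTX coordinate format plus a sidecar TSV
#' of row (trigram) and column (species) labels.
#'
#' @param A a `trigram_matrix`.
#' @param mtx_path output `.mtx` path; labels go to `<mtx_path>.labels.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_trigram_mtx <- function(A, mtx_path) {
  nz <- which(A != 0, arr.ind = TRUE)
  header <- c("%%MatrixMarket matrix coordinate real general",
              paste(nrow(A), ncol(A), nrow(nz)))
  body <- sprintf("%d %d %g", nz[, 1L], nz[, 2L], A[nz])
  writeLines(c(header, body), mtx_path)
  lab_path <- paste0(mtx_path, ".labels.tsv")
  labs <- c(paste("row", seq_len(nrow(A)), rownames(A), sep = "\t"),
            paste("col", seq_len(ncol(A)), colnames(A), sep = "\t"))
  writeLines(labs, lab_path)
  invisible(c(mtx_path, lab_path))
}
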