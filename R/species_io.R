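# Reading and writing species sequences, taxonomy tables, control lists,
# PHYLIP distance matrices and partition files.

#' Read per-species concatenated protein sequences from FASTA
#'
#' Reads a multi-FASTA amino-acid file and returns one record per species.
#' When several FASTA records belong to one species (e.g. gene families of a
#' proteome), pass `grouping` to map FASTA record ids to species ids; the
#' sequences of a species are concatenated in file order. Non-standard
#' residues (`B J O U X Z`, stops `*`, gaps `-` `.`) are removed and counted
#' per species in the `cleaning` attribute.
#'
#' @param fasta_path path to a FASTA file of amino-acid sequences.
#' @param grouping optional named character vector mapping FASTA record id ->
#'   species id. When `NULL`, each record is its own species (id = first
#'   whitespace-delimited token of the header).
#' @return A `species_dataset`: list with `records` (named list of
#'   `species_record`), and attribute `cleaning` (named list of per-species
#'   removed-symbol counts). Lineages are unset; attach them with
#'   [attach_taxonomy()].
#' @export
read_species_fasta <- function(fasta_path, grouping = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("FASTA file '", fasta_path, "' contains no records")
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (!is.null(grouping)) {
    missing <- setdiff(ids, names(grouping))
    if (length(missing) > 0L) {
      stop("grouping has no species for record(s): ",
           paste(missing, collapse = ", "))
    }
    species <- unname(grouping[ids])
  } else {
    species <- ids
  }
  raw <- split(as.character(seqs), factor(species, levels = unique(species)))
  records <- list()
  cleaning <- list()
  for (sp in names(raw)) {
    concat <- paste0(raw[[sp]], collapse = "")
    cl <- clean_sequence(concat)
    if (nchar(cl$sequence) == 0L) {
      stop("species '", sp, "' has zero residues after cleaning")
    }
    records[[sp]] <- species_record(sp, cl$sequence)
    cleaning[[sp]] <- cl$removed
  }
  new_species_dataset(records, cleaning = cleaning)
}

clean_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  removed <- table(chars[bad])
  unknown <- setdiff(names(removed), NONSTANDARD_AA)
  if (length(unknown) > 0L) {
    stop("sequence contains symbols outside the amino-acid alphabet: ",
         paste(unknown, collapse = ", "))
  }
  list(
    sequence = paste0(chars[!bad], collapse = ""),
    removed = as.list(removed)
  )
}

#' @rdname read_species_fasta
#' @param species_id unique species identifier.
#' @param sequence cleaned amino-acid sequence.
#' @param lineage optional character vector of 14 Linnaean taxon names,
#'   Superregnum first.
#' @param mnemonic optional short (<= 10 character) plotting label.
#' @export
species_record <- function(species_id, sequence, lineage = NULL,
                           mnemonic = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (!is.null(lineage)) {
    lineage <- validate_lineage(lineage, species_id)
  }
  structure(
    list(species_id = species_id, sequence = sequence,
         lineage = lineage, mnemonic = mnemonic),
    class = "species_record"
  )
}

validate_lineage <- function(lineage, species_id) {
  lineage <- as.character(lineage)
  if (length(lineage) != N_LINNAEAN_RANKS || any(!nzchar(lineage))) {
    stop("lineage for '", species_id, "' must have exactly ",
         N_LINNAEAN_RANKS, " non-empty ranks, got ", length(lineage))
  }
  lineage
}

new_species_dataset <- function(records, positive_control = character(),
                                secondary_control = NULL, cleaning = NULL) {
  stopifnot(is.list(records))
  ids <- vapply(records, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids in dataset")
  names(records) <- ids
  structure(
    list(records = records,
         positive_control = positive_control,
         secondary_control = secondary_control),
    cleaning = cleaning,
    class = "species_dataset"
  )
}

#' Assemble a dataset with control groups
#'
#' @param records list of `species_record`s (e.g. from
#'   [read_species_fasta()]).
#' @param positive_control character vector of species ids that a valid
#'   clustering must isolate in a single cluster.
#' @param secondary_control optional second control set.
#' @return a `species_dataset`.
#' @export
species_dataset <- function(records, positive_control = character(),
                            secondary_control = NULL) {
  ds <- new_species_dataset(records, positive_control, secondary_control)
  ids <- names(ds$records)
  if (length(ids) < 2L) stop("a dataset needs at least 2 species")
  for (ctl in list(positive_control, secondary_control)) {
    if (!is.null(ctl) && !all(ctl %in% ids)) {
      stop("control set contains unknown species: ",
           paste(setdiff(ctl, ids), collapse = ", "))
    }
  }
  ds
}

#' @export
print.species_dataset <- function(x, ...) {
  cat("species_dataset:", length(x$records), "species")
  if (length(x$positive_control))
    cat(";", length(x$positive_control), "positive-control species")
  cat("\n")
  invisible(x)
}

#' Read a 14-rank Linnaean taxonomy table
#'
#' Tab-separated, no header, 15 columns: species id then the 14 ranks in
#' canonical order (Superregnum first, Species last).
#'
#' @param tsv_path path to the taxonomy TSV.
#' @return named list: species id -> character(14) lineage.
#' @export
read_taxonomy <- function(tsv_path) {
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("taxonomy file is empty")
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != N_LINNAEAN_RANKS + 1L) {
      stop("taxonomy line ", i, ": expected ", N_LINNAEAN_RANKS + 1L,
           " tab-separated columns, got ", length(fields))
    }
    id <- fields[[1]]
    if (id %in% names(out)) {
      stop("taxonomy line ", i, ": duplicate species id '", id, "'")
    }
    out[[id]] <- validate_lineage(fields[-1L], id)
  }
  lineage_strings <- vapply(out, paste, character(1), collapse = "\t")
  if (anyDuplicated(lineage_strings)) {
    warning("taxonomy contains duplicated lineages under distinct ids")
  }
  out
}

#' Attach lineages (and auto-generate mnemonics) onto a dataset
#'
#' Mnemonics default to the first letter of the genus (rank 13) plus the
#' first three letters of the species epithet, de-duplicated with numeric
#' suffixes.
#'
#' @param dataset a `species_dataset`.
#' @param taxonomy named lineage list from [read_taxonomy()].
#' @return the dataset with lineages and mnemonics filled in.
#' @export
attach_taxonomy <- function(dataset, taxonomy) {
  ids <- names(dataset$records)
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing) > 0L) {
    stop("taxonomy missing for species: ", paste(missing, collapse = ", "))
  }
  for (id in ids) {
    dataset$records[[id]]$lineage <- taxonomy[[id]]
  }
  have <- !vapply(dataset$records, function(r) is.null(r$mnemonic), logical(1))
  mn <- vapply(dataset$records, function(r) {
    if (is.null(r$mnemonic)) default_mnemonic(r$lineage) else r$mnemonic
  }, character(1))
  mn <- make_unique_labels(mn)
  for (i in seq_along(ids)) dataset$records[[ids[i]]]$mnemonic <- mn[[i]]
  dataset
}

default_mnemonic <- function(lineage) {
  genus <- lineage[[13L]]
  epithet <- sub("^\\S+\\s*", "", lineage[[14L]])
  if (!nzchar(epithet)) epithet <- lineage[[14L]]
  paste0(substr(genus, 1L, 1L), substr(epithet, 1L, 3L))
}

make_unique_labels <- function(labels, width = 10L) {
  labels <- substr(labels, 1L, width)
  while (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    idx <- which(labels == dup)
    for (j in seq_along(idx)) {
      suffix <- as.character(j)
      base <- substr(dup, 1L, width - nchar(suffix))
      labels[idx[j]] <- paste0(base, suffix)
    }
  }
  labels
}

#' Write / read a PHYLIP square distance matrix
#'
#' The format consumed by PHYLIP NEIGHBOR: first line the number of taxa,
#' then one row per taxon with the label padded to 10 characters and the
#' distances printed with 6 decimals.
#'
#' @param matrix symmetric numeric matrix with zero diagonal.
#' @param labels taxon labels (truncated to 10 characters, de-duplicated).
#' @param path optional output file; when `NULL` the text is returned.
#' @return the PHYLIP text, invisibly when written to a file.
#' @export
write_phylip_distances <- function(matrix, labels = rownames(matrix),
                                   path = NULL) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (ncol(matrix) != n) stop("distance matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-9) {
    stop("distance matrix is asymmetric beyond 1e-9")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  labels <- make_unique_labels(as.character(labels))
  rows <- vapply(seq_len(n), function(i) {
    paste0(formatC(labels[i], width = -10L),
           paste(sprintf("%.6f", matrix[i, ]), collapse = " "))
  }, character(1))
  text <- paste0(paste(c(n, rows), collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(text)
}

#' @rdname write_phylip_distances
#' @export
read_phylip_distances <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[[1]]))
  mat <- matrix(0, n, n)
  labels <- character(n)
  for (i in seq_len(n)) {
    line <- lines[[i + 1L]]
    labels[i] <- trimws(substr(line, 1L, 10L))
    mat[i, ] <- as.numeric(strsplit(trimws(substr(line, 11L, nchar(line))),
                                    "\\s+")[[1]])
  }
  dimnames(mat) <- list(labels, labels)
  mat
}

#' Write / read a partition as TSV
#'
#' Columns `cluster`, `species_id`, `mnemonic`; clusters ordered by
#' descending size, ties broken by smallest member id.
#'
#' @param partition an `asap_partition` (any list of disjoint species-id
#'   vectors works).
#' @param dataset optional `species_dataset` supplying mnemonics.
#' @param path optional output file.
#' @return the TSV text (invisibly when written to `path`).
#' @export
write_partition <- function(partition, dataset = NULL, path = NULL) {
  clusters <- partition_clusters(partition)
  if (length(clusters) == 0L) stop("partition is empty")
  all_ids <- unlist(clusters)
  if (anyDuplicated(all_ids)) stop("partition clusters overlap")
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) min(sort(cl)), character(1)))
  clusters <- clusters[ord]
  rows <- character(0)
  for (ci in seq_along(clusters)) {
    for (id in sort(clusters[[ci]])) {
      mn <- if (!is.null(dataset)) dataset$records[[id]]$mnemonic else NA
      rows <- c(rows, paste(ci, id, if (is.null(mn) || is.na(mn)) "" else mn,
                            sep = "\t"))
    }
  }
  text <- paste(c("cluster\tspecies_id\tmnemonic", rows), collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  clusters <- split(df$species_id, df$cluster)
  names(clusters) <- NULL
  new_partition(clusters, provenance = list(source = path))
}

partition_clusters <- function(partition) {
  if (inherits(partition, "asap_partition")) partition$clusters else partition
}
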