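# Synthetic fixture generator: a nested Linnaean-style taxonomy plus
# protein sequences "evolved" along it by uniform residue substitution, so
# trigram-profile distance tracks lineage divergence. Clade 1 doubles as
# the positive-control group; optional outliers descend from an unrelated
# root and diverge from everything at rank 2 (the negative-control
# construction).

#' Specification for a simulated dataset
#'
#' Defaults describe a well-separated study condition: 4 clades of 5
#' species, 2000-residue proteins, 2% within-clade and 35% between-clade
#' per-site substitution probability, no outliers. Within each clade the
#' lineage is shared through rank 10 (the depth of the avian
#' positive-control group in real mitochondrial data); outliers share only
#' rank 1 with everyone else.
#'
#' @param n_clades number of planted clades (>= 2).
#' @param species_per_clade species per clade.
#' @param seq_length root protein length in residues.
#' @param within_clade_subst per-site substitution probability from clade
#'   ancestor to leaf.
#' @param between_clade_subst per-site substitution probability from root
#'   to clade ancestor; must exceed `within_clade_subst`.
#' @param n_outliers species drawn from an unrelated random root.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_clades = 4L, species_per_clade = 5L,
                     seq_length = 2000L, within_clade_subst = 0.02,
                     between_clade_subst = 0.35, n_outliers = 0L,
                     seed = 1L) {
  stopifnot(n_clades >= 2L, species_per_clade >= 1L, seq_length >= 3L,
            within_clade_subst >= 0, between_clade_subst <= 1,
            within_clade_subst < between_clade_subst ||
              (within_clade_subst == 0 && between_clade_subst == 0),
            n_clades * species_per_clade + n_outliers >= 4L)
  structure(
    list(n_clades = as.integer(n_clades),
         species_per_clade = as.integer(species_per_clade),
         seq_length = as.integer(seq_length),
         within_clade_subst = within_clade_subst,
         between_clade_subst = between_clade_subst,
         n_outliers = as.integer(n_outliers), seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# depth (in ranks) shared by the members of one simulated clade
SIM_CLADE_DEPTH <- 10L

#' Simulate a dataset of related proteomes with consistent lineages
#'
#' One random root protein is drawn; each clade ancestor derives from it by
#' between-clade substitution and each leaf from its ancestor by
#' within-clade substitution. Substitutions are uniform over the 19
#' alternative residues. Lineages of clade members agree through rank 10
#' and diverge below; each outlier descends from its own independent
#' random root (outliers are unrelated to the clades and to each other)
#' and its lineage diverges from everything at rank 2. The positive
#' control is clade 1.
#'
#' @param spec a [sim_spec()].
#' @return a `species_dataset` with lineages and mnemonics attached and
#'   `positive_control` = clade 1.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(spec$seed)
  root <- sample(AA_ALPHABET, spec$seq_length, replace = TRUE)
  records <- list()
  for (ci in seq_len(spec$n_clades)) {
    ancestor <- mutate_sequence(root, spec$between_clade_subst)
    for (si in seq_len(spec$species_per_clade)) {
      id <- sprintf("C%02dS%02d", ci, si)
      leaf <- mutate_sequence(ancestor, spec$within_clade_subst)
      records[[id]] <- species_record(
        id, paste0(leaf, collapse = ""),
        lineage = sim_lineage(ci, si), mnemonic = id)
    }
  }
  for (oi in seq_len(spec$n_outliers)) {
    id <- sprintf("OUT%02d", oi)
    leaf <- sample(AA_ALPHABET, spec$seq_length, replace = TRUE)
    records[[id]] <- species_record(
      id, paste0(leaf, collapse = ""),
      lineage = sim_outlier_lineage(oi), mnemonic = id)
  }
  species_dataset(records,
                  positive_control = sprintf("C01S%02d",
                                             seq_len(spec$species_per_clade)))
}

mutate_sequence <- function(chars, p) {
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  }
  chars
}

sim_lineage <- function(clade, species) {
  c("RootDomain", "SharedKingdom",
    sprintf("Clade%02d_R%02d", clade, 3:SIM_CLADE_DEPTH),
    sprintf("C%02dS%02d_R%02d", clade, species, (SIM_CLADE_DEPTH + 1L):13L),
    sprintf("Clade%02d species%02d", clade, species))
}

sim_outlier_lineage <- function(oi) {
  c("RootDomain",
    sprintf("Out%02d_R%02d", oi, 2:13),
    sprintf("Out%02d species", oi))
}

#' Ground-truth partition of a simulated dataset
#'
#' Clusters are the planted clades; each outlier is its own singleton.
#'
#' @param spec the [sim_spec()] used for [simulate_dataset()].
#' @param dataset the simulated dataset (used only for id validation).
#' @return an `asap_partition` carrying the planted clustering.
#' @export
planted_partition <- function(spec, dataset = NULL) {
  clusters <- lapply(seq_len(spec$n_clades), function(ci) {
    sprintf("C%02dS%02d", ci, seq_len(spec$species_per_clade))
  })
  for (oi in seq_len(spec$n_outliers)) {
    clusters[[length(clusters) + 1L]] <- sprintf("OUT%02d", oi)
  }
  if (!is.null(dataset)) {
    stopifnot(setequal(unlist(clusters), names(dataset$records)))
  }
  new_partition(clusters, provenance = list(source = "planted"))
}

#' Write a simulated dataset as FASTA + taxonomy TSV
#'
#' Emits the standard on-disk forms so simulated fixtures flow through the
#' same readers as real data.
#'
#' @param dataset a `species_dataset`.
#' @param fasta_path,taxonomy_path output paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(dataset, fasta_path, taxonomy_path) {
  ids <- names(dataset$records)
  fasta <- unlist(lapply(ids, function(id) {
    c(paste0(">", id), dataset$records[[id]]$sequence)
  }))
  writeLines(fasta, fasta_path)
  rows <- vapply(ids, function(id) {
    paste(c(id, dataset$records[[id]]$lineage), collapse = "\t")
  }, character(1))
  writeLines(rows, taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

#' Partition identity check (planted-versus-recovered)
#'
#' @param a,b partitions (or plain lists of id vectors).
#' @return `TRUE` when both contain exactly the same clusters as sets.
#' @export
same_partition <- function(a, b) {
  ca <- lapply(partition_clusters(a), sort)
  cb <- lapply(partition_clusters(b), sort)
  key <- function(cl) paste(cl, collapse = "\r")
  setequal(vapply(ca, key, character(1)), vapply(cb, key, character(1)))
}
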