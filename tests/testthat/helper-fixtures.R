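# Shared fixture builders. Everything is generated in code; nothing binary.

# tiny lineage factory: shares the first `shared` ranks with the reference
# lineage, unique below
make_lineage <- function(tag, shared = 2L,
                         ref = paste0("R", seq_len(14L))) {
  lin <- paste0(tag, "_", seq_len(14L))
  if (shared > 0L) lin[seq_len(shared)] <- ref[seq_len(shared)]
  lin
}

# the avian reference lineage (Superregnum -> Species)
aves_lineage <- function(genus = "Aythya", species = "Aythya americana") {
  c("Eukaryota", "Animalia", "Eumetazoa", "Bilateria", "Deuterostomia",
    "Chordata", "Vertebrata", "Gnathostomata", "Aves", "Carinatae",
    "Anseriformes", "Anatidae", genus, species)
}

# ten bird-like lineages agreeing through rank 10 (Subclassis) and
# diverging at rank 11
make_aves_group <- function(n = 10L) {
  lapply(seq_len(n), function(i) {
    lin <- aves_lineage(genus = paste0("Genus", i),
                        species = paste0("Genus", i, " sp", i))
    lin[11L] <- paste0("Ordo", i)
    lin[12L] <- paste0("Familia", i)
    lin
  })
}

# deterministic pseudo-protein over the 20-letter alphabet
random_protein <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(svdtax:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# small labelled distance matrix from explicit coordinates (cols = species)
dist_from_coords <- function(coords) {
  species_distances(coords)
}

# dataset of n tiny records with sequential ids and optional lineages
tiny_dataset <- function(seqs, lineages = NULL, control = character()) {
  ids <- names(seqs)
  records <- lapply(ids, function(id) {
    species_record(id, seqs[[id]],
                   lineage = if (!is.null(lineages)) lineages[[id]] else NULL)
  })
  species_dataset(records, positive_control = control)
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}

write_temp_taxonomy <- function(lineages,
                                path = tempfile(fileext = ".tsv")) {
  rows <- vapply(names(lineages), function(id) {
    paste(c(id, lineages[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  path
}
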