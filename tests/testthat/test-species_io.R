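test_that("FASTA records are grouped, concatenated and cleaned per species", {
  path <- write_temp_fasta(list(g1 = "MKV", g2 = "AMK"))
  ds <- read_species_fasta(path, grouping = c(g1 = "spA", g2 = "spA"))
  expect_named(ds$records, "spA")
  expect_equal(ds$records$spA$sequence, "MKVAMK")

  # no grouping: record id is the species id
  single <- read_species_fasta(write_temp_fasta(list(spA = "MKV")))
  expect_equal(single$records$spA$sequence, "MKV")

  # non-standard residues are removed and counted
  dirty <- read_species_fasta(write_temp_fasta(list(spB = "MKX*V")))
  expect_equal(dirty$records$spB$sequence, "MKV")
  cleaning <- attr(dirty, "cleaning")$spB
  expect_equal(cleaning$X, 1L)
  expect_equal(cleaning$`*`, 1L)
})

test_that("FASTA reader rejects empty files and all-removed sequences", {
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_species_fasta(empty))
  expect_error(
    read_species_fasta(write_temp_fasta(list(spZ = "XXX"))),
    "spZ")
})

test_that("species set is stable under record order permutation", {
  p1 <- write_temp_fasta(list(g1 = "MKV", g2 = "AMK", g3 = "CCW"))
  p2 <- write_temp_fasta(list(g3 = "CCW", g1 = "MKV", g2 = "AMK"))
  g <- c(g1 = "spA", g2 = "spA", g3 = "spB")
  d1 <- read_species_fasta(p1, g)
  d2 <- read_species_fasta(p2, g)
  expect_setequal(names(d1$records), names(d2$records))
  expect_equal(d2$records$spA$sequence, "MKVAMK")
})

test_that("taxonomy table enforces 15 columns, rank order and unique ids", {
  lin <- aves_lineage()
  path <- write_temp_taxonomy(list(Aame = lin))
  tax <- read_taxonomy(path)
  expect_equal(tax$Aame[[9]], "Aves")
  expect_equal(tax$Aame[[14]], "Aythya americana")

  # 13 taxa -> arity error with line number
  bad <- tempfile()
  writeLines(paste(c("Aame", lin[1:13]), collapse = "\t"), bad)
  expect_error(read_taxonomy(bad), "line 1")

  # duplicate ids rejected
  dup <- tempfile()
  writeLines(rep(paste(c("Aame", lin), collapse = "\t"), 2), dup)
  expect_error(read_taxonomy(dup), "duplicate")

  # duplicate lineages under distinct ids: accepted with warning
  two <- tempfile()
  writeLines(c(paste(c("Aam1", lin), collapse = "\t"),
               paste(c("Aam2", lin), collapse = "\t")), two)
  expect_warning(tax2 <- read_taxonomy(two), "duplicated lineages")
  expect_length(tax2, 2L)
})

test_that("PHYLIP distance writer round-trips and formats to spec", {
  m <- matrix(c(0, 1.5, 1.5, 0), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  txt <- write_phylip_distances(m)
  expect_equal(txt,
    "2\nA         0.000000 1.500000\nB         1.500000 0.000000\n")

  # zero matrix round-trip at n = 3
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path <- tempfile()
  write_phylip_distances(z, path = path)
  expect_equal(unname(read_phylip_distances(path)), unname(z))

  # long labels truncated to 10 chars, still unique
  long <- matrix(c(0, 2, 2, 0), 2, 2)
  txt2 <- write_phylip_distances(long,
    labels = c("averylongname_one", "averylongname_two"))
  labs <- substr(strsplit(txt2, "\n")[[1]][2:3], 1, 10)
  expect_equal(nchar(trimws(labs[1])) <= 10, TRUE)
  expect_false(labs[1] == labs[2])

  # asymmetry rejected
  asym <- matrix(c(0, 1, 1.1, 0), 2, 2)
  expect_error(write_phylip_distances(asym), "asymmetric")
})

test_that("PHYLIP writer/reader agree within 1e-6 on random matrices", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    x <- matrix(runif(n * n, 0, 50), n, n)
    m <- (x + t(x)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("sp", 1:n), paste0("sp", 1:n))
    path <- tempfile()
    write_phylip_distances(m, path = path)
    expect_lt(max(abs(read_phylip_distances(path) - m)), 1e-6)
  }
})

test_that("partition TSV writes size-ordered clusters and round-trips", {
  part <- svdtax:::new_partition(list(c("C"), c("A", "B")))
  txt <- write_partition(part)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "cluster\tspecies_id\tmnemonic")
  # cluster 1 is the larger {A, B}
  expect_match(lines[2], "^1\tA")
  expect_match(lines[3], "^1\tB")
  expect_match(lines[4], "^2\tC")

  path <- tempfile()
  write_partition(part, path = path)
  back <- read_partition(path)
  expect_true(same_partition(back, part))

  # singleton-only partition: n rows, n clusters
  singles <- svdtax:::new_partition(as.list(letters[1:4]))
  df <- utils::read.delim(textConnection(write_partition(singles)))
  expect_equal(nrow(df), 4L)
  expect_equal(length(unique(df$cluster)), 4L)

  # empty or overlapping partitions rejected
  expect_error(write_partition(list()), "empty")
  expect_error(write_partition(list(c("A", "B"), c("B"))), "overlap")
})

test_that("mnemonics default to genus initial + epithet prefix, unique", {
  lins <- list(
    Aame = aves_lineage(),
    Afer = aves_lineage(species = "Aythya ferina"),
    Hsap = c("Eukaryota", "Animalia", "Eumetazoa", "Bilateria",
             "Deuterostomia", "Chordata", "Vertebrata", "Gnathostomata",
             "Mammalia", "Theria", "Primates", "Hominidae", "Homo",
             "Homo sapiens"))
  ds <- tiny_dataset(list(Aame = "MKVMKV", Afer = "MKVMKA",
                          Hsap = "AAAMKV"))
  ds <- attach_taxonomy(ds, lins)
  mn <- vapply(ds$records, `[[`, character(1), "mnemonic")
  expect_equal(unname(mn["Hsap"]), "Hsap")
  expect_equal(unname(mn["Aame"]), "Aame")
  expect_false(anyDuplicated(mn) > 0)
})
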