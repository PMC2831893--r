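test_that("the genetic code table is complete and agrees with an independent table", {
  code <- genetic_code()
  expect_length(code$table, 64L)
  expect_length(code$sense_codons, 61L)
  expect_setequal(code$stop_codons, c("TAA", "TAG", "TGA"))
  expect_identical(code$sense_codons, sort(code$sense_codons))
  ref <- Biostrings::GENETIC_CODE
  expect_identical(unname(code$table[names(ref)]), as.character(ref))
})

test_that("FASTA alignments round-trip and malformed input errors", {
  set.seed(101)
  r <- random_codon_alignment(c("human", "mouse", "rat"), 20)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(r$aln, path)
  back <- load_alignment(path, mode = "codon")
  expect_identical(back$taxa, r$aln$taxa)
  expect_identical(back$columns, r$aln$columns)
  expect_identical(back$source_mask, r$aln$source_mask)

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(load_alignment(empty), "no records")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGATG", ">b", "ATG"), ragged)
  expect_error(load_alignment(ragged), "ragged")

  notriplet <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGA", ">b", "ATGA"), notriplet)
  expect_error(load_alignment(notriplet), "divisible by 3")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATG", ">a", "ATG"), dup)
  expect_error(load_alignment(dup), "duplicate")
})

test_that("input is case-insensitive and U reads as T", {
  aln <- codon_alignment(c(x = "augGGu", y = "ATGGGT"))
  expect_identical(aln$columns["x", ], aln$columns["y", ])
})

test_that("codon-column filtering is complete-case and tracks the source mask", {
  clean <- codon_alignment(c(a = "ATGGGTACG", b = "ATGGGAACG"))
  f <- filter_codon_columns(clean)
  expect_identical(f$columns, clean$columns)
  expect_identical(f$source_mask, 1:3)

  gapped <- codon_alignment(c(a = "ATG---ACG", b = "ATGGGAACG"))
  f <- filter_codon_columns(gapped)
  expect_identical(f$source_mask, c(1L, 3L))
  expect_equal(f$n_sites, 2L)

  withstop <- codon_alignment(c(a = "ATGTAAACG", b = "ATGGGAACG"))
  expect_error(filter_codon_columns(withstop), "stop codon")
  f <- filter_codon_columns(withstop, stop_policy = "drop")
  expect_identical(f$source_mask, c(1L, 3L))

  allbad <- codon_alignment(c(a = "NNN", b = "ATG"))
  expect_error(filter_codon_columns(allbad), "no codon columns remain")
})

test_that("filtering matches a naive per-column scan on random corrupted alignments", {
  set.seed(77)
  stops <- genetic_code()$stop_codons
  for (rep in 1:10) {
    r <- random_codon_alignment(letters[1:4], 30)
    mat <- r$aln$columns
    n_bad <- sample(3:8, 1)
    for (k in seq_len(n_bad)) {
      i <- sample(4, 1); j <- sample(30, 1)
      mat[i, j] <- sample(c("---", "ANN", "NTG", stops), 1)
    }
    aln <- codon_alignment(mat)
    keep_oracle <- vapply(seq_len(ncol(mat)), function(j) {
      all(mat[, j] %in% SENSE)
    }, logical(1))
    f <- filter_codon_columns(aln, stop_policy = "drop")
    expect_identical(f$source_mask, which(keep_oracle))
    # never grows, and the mask reproduces the filtered columns
    expect_lte(f$n_sites, aln$n_sites)
    expect_identical(f$columns, mat[, keep_oracle, drop = FALSE])
  }
})

test_that("the #<int> Newick dialect assigns branch partitions", {
  tr <- rap1_species_tree()
  expect_s3_class(tr, "clade_tree")
  expect_equal(tr$n_partitions, 2L)
  expect_equal(sum(tr$edge_partition == 1L), 3L)  # stem + two retro tips
  fg_children <- tr$phylo$edge[tr$edge_partition == 1L, 2L]
  fg_tips <- tr$phylo$tip.label[fg_children[fg_children <= 9]]
  expect_setequal(fg_tips, c("retro1", "retro2"))

  # tag after the branch length is equivalent to tag before it
  a <- load_tree("((A:0.1,B:0.2)#1:0.3,C:0.4);")
  b <- load_tree("((A:0.1,B:0.2):0.3#1,C:0.4);")
  expect_identical(a$edge_partition, b$edge_partition)

  # propagation off: only the stem branch is foreground
  c1 <- load_tree("((A:0.1,B:0.2)#1:0.3,C:0.4);", propagate = FALSE)
  expect_equal(sum(c1$edge_partition == 1L), 1L)
  expect_equal(sum(a$edge_partition == 1L), 3L)

  # a descendant's own tag overrides the propagated one
  d <- load_tree("((A#2:0.1,B:0.2)#1:0.3,C:0.4);")
  expect_setequal(unique(d$edge_partition), 0:2)

  expect_error(load_tree("((A#3:0.1,B:0.2):0.3,C:0.4);"), "contiguous")
  expect_error(load_tree("(A:-0.5,B:0.1);"), "negative|non-negative")
})

test_that("single-leaf trees parse and serialize", {
  tr <- load_tree("A:0.1;")
  expect_equal(length(tr$phylo$tip.label), 1L)
  expect_equal(tr$phylo$edge.length, 0.1)
  expect_equal(tr$n_partitions, 1L)
  expect_match(write_tree(tr), "^A:0\\.1;$")
})

test_that("trees round-trip through the dialect with 12-digit lengths", {
  set.seed(31)
  for (rep in 1:5) {
    phy <- ape::rtree(6)
    part <- integer(nrow(phy$edge))
    # label one random clade as foreground
    inner <- sample(setdiff(unique(phy$edge[, 1]), 7), 1)
    clade <- c(inner, retroclade:::.descendants(phy, inner))
    part[phy$edge[, 2] %in% clade] <- 1L
    if (!any(part == 1L)) next
    tr <- clade_tree(phy, part)
    back <- load_tree(write_tree(tr))
    expect_identical(back$phylo$tip.label, tr$phylo$tip.label)
    expect_identical(back$edge_partition, tr$edge_partition)
    expect_equal(back$phylo$edge.length, tr$phylo$edge.length,
                 tolerance = 1e-12)
  }
})

test_that("ORF translation matches an independent translator", {
  expect_identical(translate_orf("ATGGGT"), "MG")
  expect_identical(translate_orf("ACG"), "T")
  expect_identical(translate_orf("ATG"), "M")
  expect_identical(translate_orf("ATGTAA"), "M")  # terminal stop stripped
  expect_error(translate_orf("ATGTAAGGG"), "internal stop")
  expect_error(translate_orf("ATGN"), "divisible")
  expect_error(translate_orf("ATNGGN"), "A/C/G/T")
  set.seed(13)
  for (rep in 1:10) {
    orf <- paste(sample(SENSE, 25, replace = TRUE), collapse = "")
    expect_identical(
      translate_orf(orf),
      as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                         no.init.codon = TRUE))
    )
  }
})

test_that("the shipped example files load as documented", {
  fa <- system.file("extdata", "retro_site_codons.fasta",
                    package = "retroclade")
  nw <- system.file("extdata", "species_tree_labelled.nwk",
                    package = "retroclade")
  aln <- load_alignment(fa)
  expect_equal(aln$n_sites, 4L)
  expect_setequal(aln$taxa, c("rat", "mouse", "retro1", "retro2"))
  tr <- load_tree(nw)
  expect_equal(tr$n_partitions, 2L)
  expect_equal(length(tr$phylo$tip.label), 9L)
})
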