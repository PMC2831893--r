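test_that("an invariant site reconstructs with zero changes", {
  aln <- codon_alignment(setNames(rep("ATGGGT", 4), c("a", "b", "c", "d")))
  tr <- load_tree("((a:1,b:1):1,(c:1,d:1):1);")
  rec <- fitch_reconstruct(tr, aln)
  expect_equal(rec$total_changes, 0L)
  expect_true(all(rec$node_codons[, 1] == "ATG"))
  expect_true(all(rec$node_codons[, 2] == "GGT"))
  expect_equal(nrow(rec$events), 0L)
})

test_that("the retrogene diagnostic sites reconstruct with the documented events", {
  fx <- rap1_retro_site_alignment()
  rec <- annotate_cpg(classify_substitutions(
    fitch_reconstruct(fx$tree, fx$alignment, site_labels = fx$sites)
  ))
  ev <- rec$events
  # ancestral state at codon 59 is the Ala codon; one nonsynonymous change
  # (A59V) on the retro1 terminal branch
  e59 <- ev[ev$site == 59, ]
  expect_equal(nrow(e59), 1L)
  expect_identical(e59$branch, "retro1")
  expect_identical(e59$notation, "A59V")
  expect_identical(e59$class, "nonsynonymous")
  expect_identical(e59$from_codon, "GCG")
  internal <- grepl("^node", rownames(rec$node_codons))
  expect_true(all(rec$node_codons[internal, "59"] == "GCG"))
  # codon 35: synonymous T35T on retro1, nonsynonymous T35M on retro2,
  # both consistent with CpG deamination of the ancestral ACG
  e35 <- ev[ev$site == 35, ]
  expect_setequal(e35$notation, c("T35T", "T35M"))
  expect_identical(e35$branch[e35$notation == "T35T"], "retro1")
  expect_identical(e35$branch[e35$notation == "T35M"], "retro2")
  expect_true(all(e35$cpg_flag))
  # remaining retro2-specific changes
  expect_setequal(ev$notation[ev$branch == "retro2"], c("I9L", "T35M", "L96V"))
})

test_that("parsimony change counts equal exhaustive minimisation on small cases", {
  set.seed(5)
  nt <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    phy <- ape::rtree(5)
    seqs <- setNames(vapply(1:5, function(i) {
      paste(sample(nt, 12, replace = TRUE), collapse = "")
    }, character(1)), phy$tip.label)
    aln <- codon_alignment(seqs)
    rec <- fitch_reconstruct(clade_tree(phy), aln)
    total <- 0L
    for (s in 1:4) {
      for (p in 1:3) {
        ts <- match(substr(aln$columns[phy$tip.label, s], p, p), nt)
        total <- total + brute_force_parsimony(ts, phy$edge, 5L)
      }
    }
    expect_equal(rec$total_changes, total)
  }
})

test_that("change counts are invariant to leaf order and rooting", {
  set.seed(9)
  phy <- ape::rtree(6)
  r <- random_codon_alignment(phy$tip.label, 8)
  n0 <- fitch_reconstruct(clade_tree(phy), r$aln)$total_changes
  perm <- sample(6)
  aln2 <- codon_alignment(r$aln$columns[perm, , drop = FALSE])
  expect_equal(fitch_reconstruct(clade_tree(phy), aln2)$total_changes, n0)
  for (og in phy$tip.label[1:3]) {
    re <- ape::root(ape::unroot(phy), outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_reconstruct(clade_tree(re), r$aln)$total_changes, n0)
  }
})

test_that("every event joins the parent assignment to the child assignment", {
  set.seed(2)
  phy <- ape::rtree(6)
  r <- random_codon_alignment(phy$tip.label, 6)
  rec <- fitch_reconstruct(clade_tree(phy), r$aln)
  ev <- rec$events
  for (i in seq_len(nrow(ev))) {
    expect_identical(ev$from_codon[i],
                     rec$node_codons[ev$parent_node[i], as.character(ev$site[i])])
    expect_identical(ev$to_codon[i],
                     rec$node_codons[ev$child_node[i], as.character(ev$site[i])])
  }
})

test_that("parsimony never infers more changes than truly occurred", {
  tr <- calibration_tree()
  for (s in 1:5) {
    sim <- simulate_alignment(sim_config(tr, quick_params(c(0.3, 0.8)), 60,
                                         seed = 400 + s))
    rec <- fitch_reconstruct(tr, sim$alignment)
    expect_lte(rec$total_changes, nrow(sim$truth$events))
  }
})

test_that("substitution classification matches translate-and-compare on all neighbours", {
  tb <- retroclade:::codon_tables()
  pairs <- tb$pairs
  ev <- data.frame(
    branch = "x", parent_node = "p", child_node = "c",
    site = 1L, codon_pos = pairs$pos,
    from_nt = pairs$from_nt, to_nt = pairs$to_nt,
    from_codon = SENSE[pairs$i], to_codon = SENSE[pairs$j],
    stringsAsFactors = FALSE
  )
  out <- classify_substitutions(ev)
  ref <- Biostrings::GENETIC_CODE
  oracle <- ifelse(ref[out$from_codon] == ref[out$to_codon],
                   "synonymous", "nonsynonymous")
  expect_identical(out$class, unname(oracle))
  expect_false(any(out$stop_involved))
  # notation spells residue, 1-based site, residue
  expect_identical(out$notation,
                   paste0(unname(ref[out$from_codon]), 1L,
                          unname(ref[out$to_codon])))
})

test_that("CpG annotation follows the deamination rule exactly", {
  aln <- codon_alignment(c(out = "ACGAAA", par = "ACGAAA",
                           c1 = "ATGAAA", c2 = "ACGGAA"))
  tr <- load_tree("(out:1,par:1,(c1:1,c2:1):1);")
  rec <- annotate_cpg(classify_substitutions(fitch_reconstruct(tr, aln)))
  ev <- rec$events
  # ACG -> ATG: C->T followed by G => flagged
  expect_true(ev$cpg_flag[ev$to_codon == "ATG"])
  # AAA -> GAA: A->G is never a deamination signature
  expect_false(ev$cpg_flag[ev$to_codon == "GAA"])
})

test_that("missing context yields an unknown flag, not FALSE", {
  # C->T at the last base of the tracked region: downstream context unknown
  aln <- codon_alignment(c(a = "AAC", b = "AAC", c = "AAT", d = "AAT"))
  tr <- load_tree("((a:1,b:1):1,(c:1,d:1):1);")
  rec <- annotate_cpg(classify_substitutions(fitch_reconstruct(tr, aln)))
  ct <- rec$events[rec$events$from_nt == "C" & rec$events$to_nt == "T", ]
  if (nrow(ct)) expect_true(all(is.na(ct$cpg_flag)))
})
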