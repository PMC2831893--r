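test_that("zero-length branches copy the root state to every leaf", {
  phy <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  tr <- clade_tree(phy)
  sim <- simulate_alignment(sim_config(tr, quick_params(0.5), 20, seed = 6))
  m <- sim$alignment$columns
  expect_true(all(m == rep(m[1, ], each = 4)))
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("identical seeds reproduce bit-identically, different seeds differ", {
  tr <- calibration_tree()
  p <- quick_params(c(0.1, 0.5))
  s1 <- simulate_alignment(sim_config(tr, p, 50, seed = 123))
  s2 <- simulate_alignment(sim_config(tr, p, 50, seed = 123))
  s3 <- simulate_alignment(sim_config(tr, p, 50, seed = 124))
  expect_identical(s1$alignment$columns, s2$alignment$columns)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_false(identical(s1$alignment$columns, s3$alignment$columns))
})

test_that("a long branch relaxes to the stationary distribution", {
  pi <- random_pi()
  p <- codon_model_params(2, 0.6, pi)
  tr <- load_tree("A:12;")
  sim <- simulate_alignment(sim_config(tr, p, 1500, seed = 19))
  counts <- tabulate(match(sim$alignment$columns[1, ], SENSE), nbins = 61)
  gof <- suppressWarnings(stats::chisq.test(counts, p = pi))
  expect_gt(gof$p.value, 0.001)
})

test_that("the nonsynonymous event share increases with omega", {
  tr <- load_tree("A:0.6;")
  wins <- 0L
  for (s in 1:50) {
    lo <- simulate_alignment(sim_config(tr, quick_params(0.05), 100, seed = s))
    hi <- simulate_alignment(sim_config(tr, quick_params(1.0), 100, seed = s))
    share <- function(x) {
      ev <- x$truth$events
      if (nrow(ev) == 0) return(0)
      mean(!ev$synonymous)
    }
    if (share(hi) > share(lo)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("replaying the recorded events transforms parent into child states", {
  tr <- calibration_tree()
  sim <- simulate_alignment(sim_config(tr, quick_params(c(0.2, 0.8)), 60,
                                       seed = 77))
  phy <- tr$phylo
  ns <- sim$truth$node_states
  ev <- sim$truth$events
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; chd <- phy$edge[e, 2]
    b <- retroclade:::.branch_id(phy, chd)
    state <- ns[par, ]
    bev <- ev[ev$branch == b, , drop = FALSE]
    bev <- bev[order(bev$time), , drop = FALSE]
    for (i in seq_len(nrow(bev))) {
      expect_identical(SENSE[state[bev$site[i]]], bev$from_codon[i])
      state[bev$site[i]] <- match(bev$to_codon[i], SENSE)
    }
    expect_identical(state, unname(ns[chd, ]))
  }
})

test_that("the CpG overlay enriches CpG-context substitutions", {
  tr <- load_tree("A:0.5;")
  pi <- rep(1 / 61, 61)
  frac <- function(bias, seed) {
    p <- codon_model_params(2, 0.5, pi)
    s <- simulate_alignment(sim_config(tr, p, 150, seed = seed,
                                       cpg_bias = bias))
    ev <- s$truth$events
    if (nrow(ev) == 0) return(NA_real_)
    mean(ev$cpg_context)
  }
  f1 <- vapply(1:25, function(s) frac(1, s), numeric(1))
  f20 <- vapply(1:25, function(s) frac(20, 1000 + s), numeric(1))
  wt <- stats::wilcox.test(f20, f1, alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})

test_that("the retrogene scenario grafts a labelled foreground clade", {
  base <- rap1_species_tree(retro = FALSE)
  out <- simulate_retrogene_scenario(
    base, retro_branch_point = list(child = "mouse", frac = 0.5),
    dup_delay = 0.01, params = quick_params(c(0.05, 0.3)),
    n_codons = 40, seed = 5
  )
  tr <- out$tree
  expect_equal(tr$n_partitions, 2L)
  fg <- tr$phylo$edge[tr$edge_partition == 1L, 2L]
  ntip <- length(tr$phylo$tip.label)
  expect_setequal(tr$phylo$tip.label[fg[fg <= ntip]], c("retro1", "retro2"))
  expect_equal(sum(tr$edge_partition == 1L), 3L)
  expect_setequal(out$alignment$taxa, c(base$phylo$tip.label, "retro1", "retro2"))
})

test_that("a zero-length graft leaves the retrocopies identical to the graft point", {
  base <- rap1_species_tree(retro = FALSE)
  out <- simulate_retrogene_scenario(
    base, retro_branch_point = list(child = "mouse", frac = 0.5),
    dup_delay = 0, params = quick_params(c(0.05, 0.3)),
    n_codons = 30, seed = 11, retro_tip_lengths = c(0, 0)
  )
  m <- out$alignment$columns
  expect_identical(m["retro1", ], m["retro2", ])
  # the retro tips equal the state stored at their (graft) ancestor node
  phy <- out$tree$phylo
  mrca <- ape::getMRCA(phy, c("retro1", "retro2"))
  graft <- phy$edge[phy$edge[, 2] == mrca, 1]
  ns <- out$truth$node_states
  expect_identical(unname(ns["retro1", ]), unname(ns[graft, ]))
  expect_error(simulate_retrogene_scenario(
    base, retro_branch_point = list(child = "nosuchtaxon", frac = 0.5),
    dup_delay = 0, params = quick_params(c(0.05, 0.3)), n_codons = 10
  ), "graft point")
})

test_that("synthetic insertion loci carry the planted TSD and cleavage motif", {
  loc <- simulate_insertion_locus(60, 12, insert_seq = "ATGCCGTTAGCA", seed = 3)
  a <- loc$insert_interval[1]; b <- loc$insert_interval[2]
  s <- loc$sequence
  expect_identical(substr(s, a - 12 + 1, a), loc$tsd$seq)
  expect_identical(substr(s, b + 1, b + 12), loc$tsd$seq)
  # cleavage context is TTTT / A
  expect_identical(substr(s, loc$en_site - 3, loc$en_site), "TTTT")
  expect_identical(substr(s, loc$en_site + 1, loc$en_site + 1), "A")
  # no-TSD locus yields no call downstream
  loc0 <- simulate_insertion_locus(60, 0, insert_seq = "ATGCCGTTAGCA", seed = 4)
  expect_null(loc0$tsd)
  expect_null(find_tsd(loc0$sequence, loc0$insert_interval))
})
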