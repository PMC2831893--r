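# Shared fixtures and independent oracles used across the suite.

SENSE <- genetic_code()$sense_codons

# Random stationary frequencies bounded away from zero.
random_pi <- function() {
  as.numeric(prop.table(runif(61, 0.5, 1.5)))
}

# Random codon alignment (uniform over sense codons) as a codon_alignment.
random_codon_alignment <- function(taxa, n_sites) {
  states <- matrix(sample.int(61L, length(taxa) * n_sites, replace = TRUE),
                   nrow = length(taxa))
  mat <- matrix(SENSE[states], nrow = length(taxa),
                dimnames = list(taxa, NULL))
  list(aln = codon_alignment(mat), states = states)
}

# Independent likelihood oracle for a rooted balanced 4-taxon tree
# ((A,B):ti,(C,D):tj); explicit summation over root and both internal-node
# states, built on transition_probabilities() only (no pruning, no C++).
brute_force_loglik_4taxon <- function(states, bl, params) {
  rm_ <- build_rate_matrix(params, 0)
  P <- lapply(bl, function(t) transition_probabilities(rm_, t))
  lnL <- 0
  for (s in seq_len(ncol(states))) {
    a <- states[1, s]; b <- states[2, s]; c <- states[3, s]; d <- states[4, s]
    tot <- 0
    for (r in 1:61) {
      v1 <- sum(P[["ti"]][r, ] * P[["ta"]][, a] * P[["tb"]][, b])
      v2 <- sum(P[["tj"]][r, ] * P[["tc"]][, c] * P[["td"]][, d])
      tot <- tot + params$pi[r] * v1 * v2
    }
    lnL <- lnL + log(tot)
  }
  lnL
}

# Newick for the balanced 4-taxon tree with named branch lengths.
four_taxon_tree <- function(bl) {
  load_tree(sprintf("((A:%.15g,B:%.15g):%.15g,(C:%.15g,D:%.15g):%.15g);",
                    bl[["ta"]], bl[["tb"]], bl[["ti"]],
                    bl[["tc"]], bl[["td"]], bl[["tj"]]))
}

# Exhaustive minimum-change count for one 4-state character on a small tree:
# enumerate every assignment of internal-node states.
brute_force_parsimony <- function(tip_states, edge, ntip) {
  internals <- setdiff(unique(as.vector(edge)), seq_len(ntip))
  grid <- expand.grid(rep(list(1:4), length(internals)))
  nmax <- max(edge)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- integer(nmax)
    st[seq_len(ntip)] <- tip_states
    st[internals] <- as.integer(grid[g, ])
    best <- min(best, sum(st[edge[, 1]] != st[edge[, 2]]))
  }
  as.integer(best)
}

# Naive sliding-window IUPAC matcher (independent of Biostrings).
iupac_scan <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  k <- length(pv)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sv[i + j - 1L] %in% iupac[[pv[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Default small model for quick fits in tests.
quick_params <- function(omega, kappa = 2, pi = rep(1 / 61, 61)) {
  codon_model_params(kappa, omega, pi)
}
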