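# Site-pattern compression: unique codon-index columns with multiplicities.
# Rows of `states` follow the taxa order given; ties broken by first occurrence.
.compress_patterns <- function(states) {
  keys <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(keys)
  list(states = states[, first, drop = FALSE],
       weights = as.numeric(table(factor(keys, levels = keys[first]))))
}

# Integer codon states (taxa x sites) for a filtered alignment.
.codon_states <- function(aln) {
  tb <- codon_tables()
  idx <- match(aln$columns, tb$sense)
  if (anyNA(idx)) {
    stop("alignment contains gaps/ambiguities/stops; ",
         "run filter_codon_columns() first")
  }
  matrix(idx, nrow = nrow(aln$columns),
         dimnames = list(aln$taxa, NULL))
}

# Symmetrized scaled generators for all partitions, as a 61 x 61 x K array.
.qsym_cube <- function(params, n_partitions) {
  if (length(params$omega) < n_partitions) {
    stop("tree has ", n_partitions, " partitions but params carry ",
         length(params$omega), " omega value(s)")
  }
  sq <- sqrt(params$pi)
  inv <- ifelse(sq > 0, 1 / sq, 0)
  cube <- array(0, c(61, 61, n_partitions))
  for (k in seq_len(n_partitions)) {
    rm <- build_rate_matrix(params, k - 1L)
    S <- rm$Q * (sq %o% inv)
    cube[, , k] <- (S + t(S)) / 2
  }
  cube
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein-pruning log-likelihood of a filtered codon alignment on a
#' clade-labelled tree, under the partitioned codon substitution model: every
#' branch uses the transition probabilities of its partition's rate matrix.
#' Site patterns are compressed before pruning. Because the model is
#' reversible the result does not depend on where the tree is rooted.
#'
#' @param aln Filtered codon-mode [codon_alignment()].
#' @param tree [clade_tree()] whose leaf names equal the alignment taxa.
#' @param params [codon_model_params()] with one omega per tree partition.
#' @return Log-likelihood (a scalar).
#' @export
codon_log_likelihood <- function(aln, tree, params) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "clade_tree"),
            inherits(params, "codon_model_params"))
  phy <- tree$phylo
  if (!setequal(phy$tip.label, aln$taxa) ||
      length(phy$tip.label) != length(aln$taxa)) {
    stop("tree leaves and alignment taxa differ")
  }
  states <- .codon_states(aln)[phy$tip.label, , drop = FALSE]
  cp <- .compress_patterns(states)
  ntip <- length(phy$tip.label)
  if (ntip == 1L) {
    # No branches: the likelihood is the stationary probability of the data.
    return(sum(cp$weights * log(params$pi[cp$states[1L, ]])))
  }
  po <- ape::reorder.phylo(phy, "postorder")
  key_old <- paste(phy$edge[, 1], phy$edge[, 2])
  key_new <- paste(po$edge[, 1], po$edge[, 2])
  part <- tree$edge_partition[match(key_new, key_old)]
  cube <- .qsym_cube(params, max(part) + 1L)
  .cpp_prune_loglik(
    tip_states = cp$states - 1L,
    weights = cp$weights,
    edges = po$edge,
    edge_len = po$edge.length,
    edge_part = as.integer(part),
    Qsym = cube,
    pi = params$pi,
    root = ntip + 1L
  )
}

# Precomputed pieces for repeated likelihood evaluations on fixed data
# (pattern compression, postorder edge permutation). The optimiser only swaps
# parameters and branch lengths, so everything else is built once.
.loglik_context <- function(aln, tree) {
  phy <- tree$phylo
  if (!setequal(phy$tip.label, aln$taxa) ||
      length(phy$tip.label) != length(aln$taxa)) {
    stop("tree leaves and alignment taxa differ")
  }
  states <- .codon_states(aln)[phy$tip.label, , drop = FALSE]
  cp <- .compress_patterns(states)
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  list(
    tip_states = cp$states - 1L,
    weights = cp$weights,
    edges = po$edge,
    perm = perm,
    part_po = as.integer(tree$edge_partition[perm]),
    n_part = max(tree$edge_partition) + 1L,
    ntip = ntip,
    n_edge = nrow(phy$edge),
    n_patterns = length(cp$weights)
  )
}

# Evaluate lnL for a context with explicit kappa, per-partition omega vector,
# stationary frequencies and branch lengths (in original edge order).
.loglik_eval <- function(ctx, kappa, omega, pi, bl) {
  params <- codon_model_params(kappa, omega, pi)
  cube <- .qsym_cube(params, ctx$n_part)
  .cpp_prune_loglik(
    tip_states = ctx$tip_states,
    weights = ctx$weights,
    edges = ctx$edges,
    edge_len = bl[ctx$perm],
    edge_part = ctx$part_po,
    Qsym = cube,
    pi = pi,
    root = ctx$ntip + 1L
  )
}
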