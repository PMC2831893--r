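# Fitch parsimony on one nucleotide character (states 1..4 = A,C,G,T).
# Returns per-node assignments, the minimal change count, and the full
# ambiguity sets from the bottom-up pass. `edges_post` / `edges_pre` are the
# edge matrix in post- and preorder; tip_state is indexed by node id.
.fitch_one <- function(tip_state, edges_post, edges_pre, ntip, root) {
  nnode <- max(edges_post)
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tip_state[i]
  count <- 0L
  # Bottom-up: process children into parents in postorder.
  kids <- split(edges_post[, 2L], edges_post[, 1L])
  # Process each parent only once all its children's subtrees are complete:
  # order parents by the last postorder row in which they appear.
  last_row <- tapply(seq_len(nrow(edges_post)), edges_post[, 1L], max)
  order_nodes <- as.integer(names(sort(last_row)))
  for (nd in order_nodes) {
    cur <- NULL
    for (ch in kids[[as.character(nd)]]) {
      cur <- if (is.null(cur)) sets[[ch]] else {
        inter <- intersect(cur, sets[[ch]])
        if (length(inter)) inter else {
          count <- count + 1L
          union(cur, sets[[ch]])
        }
      }
    }
    sets[[nd]] <- sort(cur)
  }
  # Top-down refinement: parent-matching state when available, else the
  # smallest state id (deterministic tie-break).
  assign <- integer(nnode)
  assign[root] <- sets[[root]][1L]
  for (e in seq_len(nrow(edges_pre))) {
    par <- edges_pre[e, 1L]; chd <- edges_pre[e, 2L]
    s <- sets[[chd]]
    assign[chd] <- if (assign[par] %in% s) assign[par] else s[1L]
  }
  list(assign = assign, count = count, sets = sets)
}

#' Maximum-parsimony ancestral codon reconstruction
#'
#' Reconstructs codons at the internal nodes of a rooted tree by applying
#' Fitch parsimony to each of the three nucleotide positions of each tracked
#' codon site, then assembling the per-position states into codons. Ambiguity
#' sets from the bottom-up pass are retained; the reported single assignment
#' uses the standard parent-matching refinement. Substitution events are
#' placed on the branches where parent and child assignments differ.
#'
#' @param tree A [clade_tree()] (or `phylo`); used as rooted as given.
#' @param aln A codon-mode [codon_alignment()] whose taxa are the tree leaves.
#' @param sites Codon sites (1-based column indices) to reconstruct; default
#'   all.
#' @param site_labels Residue numbers to report for the tracked sites
#'   (default `sites`); useful when the alignment itself is a pre-extracted
#'   subset of a longer ORF, so notations keep the original numbering.
#' @return Object of class `mp_reconstruction`: list with `node_codons`
#'   (character matrix, node x tracked site), `events` (data frame of
#'   [classify_substitutions()]-ready substitution events), `total_changes`
#'   (minimal nucleotide change count over tracked sites), `ambiguity`
#'   (per site, per position list of candidate-state sets), `sites`, `tree`.
#' @export
fitch_reconstruct <- function(tree, aln, sites = NULL, site_labels = NULL) {
  if (inherits(tree, "clade_tree")) tree <- tree$phylo
  stopifnot(inherits(tree, "phylo"), inherits(aln, "codon_alignment"))
  if (aln$mode != "codon") stop("codon-mode alignment required")
  ntip <- length(tree$tip.label)
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree leaves and alignment taxa differ")
  }
  if (is.null(sites)) sites <- seq_len(aln$n_sites)
  if (any(sites < 1L | sites > aln$n_sites)) stop("tracked site out of range")
  if (is.null(site_labels)) site_labels <- sites
  stopifnot(length(site_labels) == length(sites))
  nt <- c("A", "C", "G", "T")
  cols <- aln$columns[tree$tip.label, sites, drop = FALSE]
  if (any(grepl("[^ACGT]", cols))) {
    stop("leaf missing a tracked site (gap or ambiguity in tracked column)")
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  node_codons <- matrix(NA_character_, nnode, length(sites))
  rownames(node_codons) <- c(tree$tip.label,
                             paste0("node", seq(ntip + 1L, nnode)))
  colnames(node_codons) <- as.character(site_labels)
  total <- 0L
  ambiguity <- vector("list", length(sites))
  ev <- list()
  for (si in seq_along(sites)) {
    pos_assign <- matrix(NA_integer_, nnode, 3L)
    amb <- vector("list", 3L)
    for (p in 1:3) {
      tip_state <- match(substr(cols[, si], p, p), nt)
      f <- .fitch_one(tip_state, post, pre, ntip, root)
      pos_assign[, p] <- f$assign
      total <- total + f$count
      amb[[p]] <- f$sets
    }
    ambiguity[[si]] <- amb
    node_codons[, si] <- paste0(nt[pos_assign[, 1]], nt[pos_assign[, 2]],
                                nt[pos_assign[, 3]])
    for (e in seq_len(nrow(pre))) {
      par <- pre[e, 1L]; chd <- pre[e, 2L]
      pc <- node_codons[par, si]; cc <- node_codons[chd, si]
      if (pc != cc) {
        dpos <- which(strsplit(pc, "")[[1]] != strsplit(cc, "")[[1]])
        for (p in dpos) {
          ev[[length(ev) + 1L]] <- data.frame(
            branch = .branch_id(tree, chd),
            parent_node = rownames(node_codons)[par],
            child_node = rownames(node_codons)[chd],
            site = site_labels[si], codon_pos = p,
            from_nt = substr(pc, p, p), to_nt = substr(cc, p, p),
            from_codon = pc, to_codon = cc,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(0), parent_node = character(0),
               child_node = character(0), site = integer(0),
               codon_pos = integer(0), from_nt = character(0),
               to_nt = character(0), from_codon = character(0),
               to_codon = character(0))
  structure(
    list(node_codons = node_codons, events = events, total_changes = total,
         ambiguity = ambiguity, sites = sites, site_labels = site_labels,
         tree = tree),
    class = "mp_reconstruction"
  )
}

#' @export
print.mp_reconstruction <- function(x, ...) {
  cat(sprintf("<mp_reconstruction> %d tracked codon site(s), %d minimal nucleotide change(s)\n",
              length(x$sites), x$total_changes))
  invisible(x)
}

#' Classify reconstructed substitutions
#'
#' Adds synonymous/nonsynonymous class and residue notation to the events of
#' a parsimony reconstruction by translating the parent and child codons. The
#' notation uses 1-based residue numbering: nonsynonymous changes read like
#' `"T35M"`, synonymous ones repeat the residue (`"T35T"`). Events whose
#' parent or child codon is a stop are flagged in `stop_involved` rather than
#' dropped.
#'
#' @param recon An [fitch_reconstruct()] result (or its `events` data frame).
#' @param code A [genetic_code()].
#' @return The reconstruction (or data frame) with `class`
#'   (`"synonymous"`/`"nonsynonymous"`), `notation`, and `stop_involved`
#'   columns added to the events.
#' @export
classify_substitutions <- function(recon, code = genetic_code()) {
  ev <- if (inherits(recon, "mp_reconstruction")) recon$events else recon
  if (nrow(ev)) {
    aa_from <- unname(code$table[ev$from_codon])
    aa_to <- unname(code$table[ev$to_codon])
    ev$class <- ifelse(aa_from == aa_to, "synonymous", "nonsynonymous")
    ev$notation <- paste0(aa_from, ev$site, aa_to)
    ev$stop_involved <- aa_from == "*" | aa_to == "*"
    if (any(ev$stop_involved)) {
      warning(sum(ev$stop_involved), " substitution(s) involve a stop codon")
    }
  } else {
    ev$class <- character(0)
    ev$notation <- character(0)
    ev$stop_involved <- logical(0)
  }
  if (inherits(recon, "mp_reconstruction")) {
    recon$events <- ev
    recon
  } else {
    ev
  }
}

#' Annotate CpG-deamination-consistent substitutions
#'
#' Flags reconstructed substitution events that are consistent with
#' deamination of methylated CpG: a C->T change whose C is followed by G in
#' the parent-node context, or a G->A change whose G is preceded by C. The
#' context is read from full-length nucleotide sequences at the nodes
#' (reconstructed or simulated); when the required neighbour lies outside the
#' supplied context the flag is `NA` (unknown), never silently `FALSE`.
#'
#' @param recon An [fitch_reconstruct()] (+[classify_substitutions()]) result.
#' @param context_seqs Named character vector of full-length nucleotide
#'   sequences per node (names matching `rownames(recon$node_codons)`).
#'   Defaults to sequences assembled from the reconstruction itself when all
#'   codon sites were tracked.
#' @return The reconstruction with a logical `cpg_flag` column on the events.
#' @export
annotate_cpg <- function(recon, context_seqs = NULL) {
  stopifnot(inherits(recon, "mp_reconstruction"))
  original_coords <- !is.null(context_seqs)
  if (is.null(context_seqs)) {
    # Context assembled from the tracked codons themselves; adjacent tracked
    # codons are treated as adjacent in sequence, so with a subset of sites
    # only within-codon contexts are meaningful (ends report NA).
    context_seqs <- apply(recon$node_codons, 1L, paste, collapse = "")
  }
  ev <- recon$events
  flag <- rep(NA, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    ctx <- context_seqs[[ev$parent_node[i]]]
    if (is.null(ctx) || is.na(ctx)) next
    site_pos <- if (original_coords) ev$site[i] else
      match(ev$site[i], recon$site_labels)
    k <- (site_pos - 1L) * 3L + ev$codon_pos[i]  # 1-based nt coordinate
    subset_tracked <- !original_coords &&
      length(recon$sites) < max(recon$sites)
    if (ev$from_nt[i] == "C" && ev$to_nt[i] == "T") {
      cross <- ev$codon_pos[i] == 3L && subset_tracked
      flag[i] <- if (k + 1L > nchar(ctx) || cross) NA else
        substr(ctx, k + 1L, k + 1L) == "G"
    } else if (ev$from_nt[i] == "G" && ev$to_nt[i] == "A") {
      cross <- ev$codon_pos[i] == 1L && subset_tracked
      flag[i] <- if (k - 1L < 1L || cross) NA else
        substr(ctx, k - 1L, k - 1L) == "C"
    } else {
      flag[i] <- FALSE
    }
  }
  ev$cpg_flag <- flag
  recon$events <- ev
  recon
}
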