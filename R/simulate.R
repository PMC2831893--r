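#' Simulation configuration
#'
#' Bundles everything the codon-evolution simulator needs: the clade-labelled
#' tree, model parameters (one omega per partition), the number of codon
#' sites, a seed, and an optional CpG-deamination overlay. The overlay
#' multiplies the rate of every single-nucleotide C->T change whose C is
#' followed by G, and every G->A change whose G is preceded by C, by
#' `cpg_bias` (contexts are re-evaluated after every event, across codon
#' boundaries; the first and last base use the fixed flanking bases in
#' `flank`). `cpg_bias = 1` disables the overlay.
#'
#' @param tree A [clade_tree()].
#' @param params [codon_model_params()] with one omega per tree partition.
#' @param n_codons Number of codon sites, >= 1.
#' @param seed Integer seed; recorded in the output provenance.
#' @param cpg_bias CpG-deamination rate multiplier, >= 1.
#' @param flank Two single bases giving the 5' and 3' context outside the ORF.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree, params, n_codons, seed = 1L, cpg_bias = 1,
                       flank = c("A", "A")) {
  stopifnot(inherits(tree, "clade_tree"), inherits(params, "codon_model_params"))
  n_codons <- as.integer(n_codons)
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (!is.numeric(cpg_bias) || cpg_bias < 1) stop("cpg_bias must be >= 1")
  if (length(params$omega) < tree$n_partitions) {
    stop("params carry fewer omegas than tree partitions")
  }
  stopifnot(length(flank) == 2L, all(flank %in% c("A", "C", "G", "T")))
  structure(list(tree = tree, params = params, n_codons = n_codons,
                 seed = as.integer(seed), cpg_bias = cpg_bias, flank = flank),
            class = "sim_config")
}

# One branch of exact stochastic simulation. `codons` is an integer vector of
# sense-codon indices. Returns the final state plus the event log. The
# Gillespie loop keeps per-site total rates current, so the CpG overlay's
# context dependence (which couples neighbouring sites) is handled exactly.
.sim_branch <- function(codons, Q, t, cpg_bias, flank, tb) {
  L <- length(codons)
  nbr <- tb$neighbours
  chars <- tb$codon_chars
  aa <- tb$aa

  nt_at <- function(cods, k) {
    # k: 1-based position in the nucleotide sequence of length 3L (+flanks).
    if (k < 1L) return(flank[1])
    if (k > 3L * L) return(flank[2])
    site <- (k - 1L) %/% 3L + 1L
    chars[cods[site], (k - 1L) %% 3L + 1L]
  }
  # Candidate rates for one site given current context.
  site_rates <- function(cods, s) {
    nb <- nbr[[cods[s]]]
    r <- Q[cods[s], nb$j]
    if (cpg_bias > 1) {
      k <- (s - 1L) * 3L + nb$pos  # nt coordinate of each candidate change
      from <- chars[cods[s], nb$pos]
      ct <- from == "C" & nb$to == "T"
      ga <- from == "G" & nb$to == "A"
      if (any(ct)) {
        nxt <- vapply(k[ct] + 1L, function(z) nt_at(cods, z), character(1))
        r[ct][nxt == "G"] <- r[ct][nxt == "G"] * cpg_bias
      }
      if (any(ga)) {
        prv <- vapply(k[ga] - 1L, function(z) nt_at(cods, z), character(1))
        r[ga][prv == "C"] <- r[ga][prv == "C"] * cpg_bias
      }
    }
    r
  }

  rates <- lapply(seq_len(L), function(s) site_rates(codons, s))
  tot <- vapply(rates, sum, numeric(1))
  cap <- max(16L, ceiling(2 * L * t) + 16L)
  ev_time <- ev_site <- ev_pos <- numeric(cap)
  ev_from <- ev_to <- integer(cap)
  ev_cpg <- logical(cap)
  n_ev <- 0L
  tcur <- 0
  repeat {
    R <- sum(tot)
    if (R <= 0) break
    tcur <- tcur + rexp(1L, R)
    if (tcur > t) break
    s <- sample.int(L, 1L, prob = tot)
    nb <- nbr[[codons[s]]]
    pick <- sample.int(length(nb$j), 1L, prob = rates[[s]])
    from <- codons[s]
    to <- nb$j[pick]
    pos <- nb$pos[pick]
    # CpG context of the event, recorded regardless of the bias setting.
    k <- (s - 1L) * 3L + pos
    fn <- chars[from, pos]
    tn <- nb$to[pick]
    cpg <- (fn == "C" && tn == "T" && nt_at(codons, k + 1L) == "G") ||
      (fn == "G" && tn == "A" && nt_at(codons, k - 1L) == "C")
    codons[s] <- to
    n_ev <- n_ev + 1L
    if (n_ev > cap) {  # amortised growth
      cap <- cap * 2L
      length(ev_time) <- cap; length(ev_site) <- cap; length(ev_pos) <- cap
      length(ev_from) <- cap; length(ev_to) <- cap; length(ev_cpg) <- cap
    }
    ev_time[n_ev] <- tcur; ev_site[n_ev] <- s; ev_pos[n_ev] <- pos
    ev_from[n_ev] <- from; ev_to[n_ev] <- to; ev_cpg[n_ev] <- cpg
    # Refresh rates at the site and (for the context overlay) its neighbours.
    upd <- if (cpg_bias > 1) intersect(seq_len(L), (s - 1L):(s + 1L)) else s
    for (u in upd) {
      rates[[u]] <- site_rates(codons, u)
      tot[u] <- sum(rates[[u]])
    }
  }
  keep <- seq_len(n_ev)
  ev_time <- ev_time[keep]; ev_site <- ev_site[keep]; ev_pos <- ev_pos[keep]
  ev_from <- ev_from[keep]; ev_to <- ev_to[keep]; ev_cpg <- ev_cpg[keep]
  events <- data.frame(
    time = ev_time, site = as.integer(ev_site),
    codon_pos = as.integer(ev_pos),
    from_codon = tb$sense[ev_from], to_codon = tb$sense[ev_to],
    from_nt = chars[cbind(ev_from, as.integer(ev_pos))],
    to_nt = chars[cbind(ev_to, as.integer(ev_pos))],
    synonymous = aa[ev_from] == aa[ev_to],
    cpg_context = ev_cpg,
    stringsAsFactors = FALSE
  )
  list(codons = codons, events = events)
}

# Human-readable branch id: child tip label or "node<N>".
.branch_id <- function(phy, child) {
  ntip <- length(phy$tip.label)
  if (child <= ntip) phy$tip.label[child] else paste0("node", child)
}

#' Simulate a codon alignment along a tree
#'
#' Exact event-by-event (Gillespie) simulation of codon evolution under the
#' partitioned substitution model: root codons are drawn from the stationary
#' distribution and every branch evolves under its partition's rate matrix,
#' with the optional CpG-deamination overlay applied at the nucleotide level.
#' Every substitution event is recorded, so per-branch synonymous /
#' nonsynonymous / CpG-context counts exist as ground truth alongside the
#' leaf alignment.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_result`: `alignment` (a [codon_alignment()]),
#'   `truth` (list with `events` data frame, `branch_counts`, `node_states`
#'   codon-index matrix, per-partition true omega, `seed`), and `tree`.
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tb <- codon_tables()
  phy <- cfg$tree$phylo
  ntip <- length(phy$tip.label)
  Qs <- lapply(seq_len(cfg$tree$n_partitions) - 1L,
               function(k) build_rate_matrix(cfg$params, k)$Q)
  with_seed(cfg$seed, {
    root_state <- sample.int(61L, cfg$n_codons, replace = TRUE,
                             prob = cfg$params$pi)
    if (ntip == 1L) {
      sim <- .sim_branch(root_state, Qs[[cfg$tree$edge_partition[1] + 1L]],
                         phy$edge.length[1], cfg$cpg_bias, cfg$flank, tb)
      node_states <- rbind(sim$codons, root_state)
      rownames(node_states) <- c(phy$tip.label, "node2")
      ev <- sim$events
      if (nrow(ev)) {
        ev$branch <- phy$tip.label[1]
        ev$partition <- cfg$tree$edge_partition[1]
      }
      events <- ev
    } else {
      nnode <- ntip + phy$Nnode
      node_states <- matrix(NA_integer_, nnode, cfg$n_codons)
      root <- ntip + 1L
      node_states[root, ] <- root_state
      cw <- ape::reorder.phylo(phy, "cladewise")
      perm <- match(paste(cw$edge[, 1], cw$edge[, 2]),
                    paste(phy$edge[, 1], phy$edge[, 2]))
      events_list <- list()
      for (r in seq_len(nrow(cw$edge))) {
        par <- cw$edge[r, 1L]; chd <- cw$edge[r, 2L]
        part <- cfg$tree$edge_partition[perm[r]]
        sim <- .sim_branch(node_states[par, ], Qs[[part + 1L]],
                           cw$edge.length[r], cfg$cpg_bias, cfg$flank, tb)
        node_states[chd, ] <- sim$codons
        if (nrow(sim$events)) {
          sim$events$branch <- .branch_id(phy, chd)
          sim$events$partition <- part
          events_list[[length(events_list) + 1L]] <- sim$events
        }
      }
      events <- if (length(events_list)) do.call(rbind, events_list) else
        data.frame(time = numeric(0), site = integer(0), codon_pos = integer(0),
                   from_codon = character(0), to_codon = character(0),
                   from_nt = character(0), to_nt = character(0),
                   synonymous = logical(0), cpg_context = logical(0),
                   branch = character(0), partition = integer(0))
      rownames(node_states) <- c(phy$tip.label,
                                 paste0("node", seq(ntip + 1L, nnode)))
    }
    NULL
  })
  seqs <- node_states[seq_len(ntip), , drop = FALSE]
  mat <- matrix(tb$sense[seqs], nrow = ntip,
                dimnames = list(phy$tip.label, NULL))
  aln <- codon_alignment(mat)
  counts <- if (nrow(events)) {
    agg <- split(events, events$branch)
    do.call(rbind, lapply(names(agg), function(b) {
      e <- agg[[b]]
      data.frame(branch = b, n_events = nrow(e),
                 n_synonymous = sum(e$synonymous),
                 n_nonsynonymous = sum(!e$synonymous),
                 n_cpg_context = sum(e$cpg_context),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(branch = character(0), n_events = integer(0),
               n_synonymous = integer(0), n_nonsynonymous = integer(0),
               n_cpg_context = integer(0))
  }
  structure(
    list(alignment = aln,
         truth = list(events = events, branch_counts = counts,
                      node_states = node_states,
                      omega = cfg$params$omega, seed = cfg$seed,
                      cpg_bias = cfg$cpg_bias),
         tree = cfg$tree),
    class = "sim_result"
  )
}

#' Simulate a retrogene emergence scenario
#'
#' Grafts a retrogene clade onto a species tree -- a retrotransposition event
#' at a point on an existing branch, followed by a duplication event after
#' `dup_delay` expected synonymous-scale substitutions per codon -- labels the
#' grafted clade as foreground (partition 1), and simulates codon evolution
#' with background `omega[1]` and foreground `omega[2]`.
#'
#' @param base_tree A [clade_tree()] (its labels are ignored; the grafted
#'   clade defines the foreground).
#' @param retro_branch_point List `list(child=, frac=)`: the graft sits on the
#'   branch subtending node/tip `child`, a fraction `frac` of the branch
#'   length above (rootward of) that node.
#' @param dup_delay Stem length between retrotransposition and duplication.
#' @param params,n_codons,seed,cpg_bias,flank As in [sim_config()].
#' @param retro_names Names of the two retrocopy tips.
#' @param retro_tip_lengths Branch lengths of the two post-duplication tips.
#' @return A `sim_result` (see [simulate_alignment()]) whose `tree` is the
#'   grafted two-partition tree; `truth$scenario` records the event geometry.
#' @export
simulate_retrogene_scenario <- function(base_tree, retro_branch_point,
                                        dup_delay, params, n_codons,
                                        seed = 1L, cpg_bias = 1,
                                        flank = c("A", "A"),
                                        retro_names = c("retro1", "retro2"),
                                        retro_tip_lengths = c(0.03, 0.03)) {
  stopifnot(inherits(base_tree, "clade_tree"), dup_delay >= 0)
  phy <- base_tree$phylo
  child <- retro_branch_point$child
  frac <- retro_branch_point$frac %||% 0.5
  where <- if (is.character(child)) {
    w <- match(child, phy$tip.label)
    if (is.na(w)) stop("graft point '", child, "' is not a tip of the tree")
    w
  } else as.integer(child)
  host_edge <- which(phy$edge[, 2L] == where)
  if (length(host_edge) != 1L) stop("graft point outside tree")
  pos <- frac * phy$edge.length[host_edge]
  sub <- ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g):%.12g;",
                                       retro_names[1], retro_tip_lengths[1],
                                       retro_names[2], retro_tip_lengths[2],
                                       dup_delay))
  sub$root.edge <- dup_delay
  grafted <- ape::bind.tree(phy, sub, where = where, position = pos)
  mrca <- ape::getMRCA(grafted, retro_names)
  clade_nodes <- c(mrca, .descendants(grafted, mrca))
  part <- as.integer(grafted$edge[, 2L] %in% clade_nodes)
  gtree <- clade_tree(grafted, part)
  cfg <- sim_config(gtree, params, n_codons, seed = seed,
                    cpg_bias = cpg_bias, flank = flank)
  out <- simulate_alignment(cfg)
  out$truth$scenario <- list(
    retro_branch_point = list(child = child, frac = frac),
    dup_delay = dup_delay,
    retro_names = retro_names,
    retro_tip_lengths = retro_tip_lengths
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a genomic insertion locus with a planted retrocopy
#'
#' Builds a synthetic genomic segment containing a retrocopy insertion with
#' the hallmarks of L1-endonuclease-mediated retrotransposition: the
#' endonuclease cleavage motif (TTTT/A) planted at the cut point, and the
#' insert flanked by two exact copies of a target-site duplication (TSD) of
#' the requested length. Ground-truth coordinates are recorded (0-based,
#' half-open) so detection code can be validated against the plant. The
#' generator also guarantees the planted TSD is not extendable by chance, so
#' its length is exactly recoverable.
#'
#' @param flank_len Length of the random flank on each side, >= 10.
#' @param tsd_len TSD length, >= 0 (0 plants no duplication).
#' @param insert_seq The inserted (retrocopy) sequence, non-empty.
#' @param seed Integer seed.
#' @return Object of class `synthetic_locus`: list with `sequence`,
#'   `insert_interval` (0-based half-open, the insert proper),
#'   `tsd` (list: `seq`, `interval5`, `interval3`) or `NULL`,
#'   `en_site` (0-based cleavage point), `strand`, `seed`.
#' @export
simulate_insertion_locus <- function(flank_len, tsd_len, insert_seq,
                                     seed = 1L) {
  stopifnot(flank_len >= 10L, tsd_len >= 0L, nchar(insert_seq) >= 1L)
  insert_seq <- .norm_nt(insert_seq)
  if (grepl("[^ACGT]", insert_seq)) stop("insert must be plain A/C/G/T")
  nt <- c("A", "C", "G", "T")
  with_seed(seed, {
    left <- paste(sample(nt, flank_len, replace = TRUE), collapse = "")
    right_first <- sample(setdiff(nt, "T"), 1L)  # blocks chance TSD extension
    right <- paste0(right_first,
                    paste(sample(nt, flank_len - 1L, replace = TRUE),
                          collapse = ""))
    tsd <- if (tsd_len >= 1L) {
      paste0("A", paste(sample(nt, tsd_len - 1L, replace = TRUE),
                        collapse = ""))
    } else ""
    NULL
  })
  seq <- paste0(left, "TTTT", tsd, insert_seq, tsd, right)
  en_site <- flank_len + 4L
  a <- en_site + tsd_len                      # insert start (0-based)
  b <- a + nchar(insert_seq)                  # insert end (exclusive)
  structure(
    list(
      sequence = seq,
      insert_interval = c(a, b),
      tsd = if (tsd_len >= 1L) {
        list(seq = tsd, interval5 = c(a - tsd_len, a), interval3 = c(b, b + tsd_len))
      } else NULL,
      en_site = en_site,
      strand = "+",
      seed = as.integer(seed)
    ),
    class = "synthetic_locus"
  )
}
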