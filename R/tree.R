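#' Construct a clade-labelled tree
#'
#' Wraps an `ape::phylo` tree together with an integer partition label per
#' branch. Partition 0 is the background; higher ids mark foreground clades
#' (the two-clades model uses partitions {0, 1}). Labels must occupy a
#' contiguous set `0..K-1`.
#'
#' @param phylo An `ape::phylo` object.
#' @param edge_partition Integer vector, one entry per row of `phylo$edge`
#'   (default all background).
#' @return Object of class `clade_tree`: list with `phylo`, `edge_partition`,
#'   `n_partitions`.
#' @export
clade_tree <- function(phylo, edge_partition = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  ne <- nrow(phylo$edge)
  if (is.null(edge_partition)) edge_partition <- integer(ne)
  edge_partition <- as.integer(edge_partition)
  if (length(edge_partition) != ne) {
    stop("edge_partition must have one entry per branch (", ne, ")")
  }
  if (is.null(phylo$edge.length)) phylo$edge.length <- rep(0, ne)
  if (any(!is.finite(phylo$edge.length)) || any(phylo$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (anyDuplicated(phylo$tip.label)) stop("duplicate leaf names")
  parts <- sort(unique(edge_partition))
  if (!identical(parts, seq_along(parts) - 1L)) {
    stop("partition labels must form a contiguous set {0..K-1}, got {",
         paste(parts, collapse = ","), "}")
  }
  structure(
    list(phylo = phylo, edge_partition = edge_partition,
         n_partitions = length(parts)),
    class = "clade_tree"
  )
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("<clade_tree> %d tips, %d branches, %d partition(s)\n",
              length(x$phylo$tip.label), nrow(x$phylo$edge), x$n_partitions))
  invisible(x)
}

# Strip a trailing "#<int>" tag from a label; returns list(label, part or NA).
.split_part_tag <- function(lab) {
  m <- regmatches(lab, regexpr("#([0-9]+)\\s*$", lab))
  if (length(m) == 0L || is.na(lab)) {
    return(list(label = lab, part = NA_integer_))
  }
  list(label = sub("#[0-9]+\\s*$", "", lab),
       part = as.integer(sub("#", "", m)))
}

#' Parse a Newick tree with foreground branch labels
#'
#' Reads Newick where a `#<int>` tag attached to a node (either directly after
#' the name / closing parenthesis, or after the branch length, as in
#' `(A:0.1,B:0.1)#1:0.2`) assigns that branch to a partition. Unlabelled
#' branches are background (partition 0). With `propagate = TRUE` (the
#' default, matching a whole-clade foreground) a label on an internal branch
#' is inherited by its entire subtree unless a descendant carries its own tag;
#' with `propagate = FALSE` only the tagged branch itself is foreground.
#'
#' @param text Newick string, or path to a file containing one.
#' @param propagate Propagate internal-branch labels to their subtree?
#' @return A [clade_tree()].
#' @export
load_tree <- function(text, propagate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[();]", text) || (file.exists(text) && !grepl(";", text))) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  # Normalise ":<len>#<k>" (tag after branch length) to "#<k>:<len>".
  text <- gsub(":\\s*([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)\\s*#([0-9]+)",
               "#\\3:\\1", text)
  if (!grepl("\\(", text)) {
    # Single-leaf tree, e.g. "A:0.1;" -- below ape's remit, built by hand.
    body <- sub(";\\s*$", "", text)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    tag <- .split_part_tag(parts[1])
    len <- if (length(parts) > 1L) as.numeric(parts[2]) else 0
    if (is.na(len) || len < 0) stop("invalid branch length in '", text, "'")
    phy <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = tag$label,
           Nnode = 1L, edge.length = len),
      class = "phylo", order = "cladewise"
    )
    part <- if (is.na(tag$part)) 0L else tag$part
    return(clade_tree(phy, part))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL)
  if (is.null(phy)) stop("unparseable Newick: ", text)
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  node_lab <- if (!is.null(phy$node.label)) phy$node.label else rep("", nnode)
  raw <- rep(NA_integer_, ntip + nnode)
  for (i in seq_len(ntip)) {
    sp <- .split_part_tag(phy$tip.label[i])
    phy$tip.label[i] <- sp$label
    raw[i] <- sp$part
  }
  for (j in seq_len(nnode)) {
    sp <- .split_part_tag(node_lab[j])
    node_lab[j] <- sp$label
    raw[ntip + j] <- sp$part
  }
  phy$node.label <- if (any(nzchar(node_lab))) node_lab else NULL
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch length")
  }
  edge <- phy$edge
  part <- integer(nrow(edge))
  # read.tree returns cladewise (parent-before-child) edge order, so a single
  # forward sweep implements subtree propagation.
  parent_edge <- match(edge[, 1L], edge[, 2L])
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2L]
    if (!is.na(raw[child])) {
      part[e] <- raw[child]
    } else if (propagate && !is.na(parent_edge[e])) {
      part[e] <- part[parent_edge[e]]
    } else {
      part[e] <- 0L
    }
  }
  clade_tree(phy, part)
}

#' Serialize a clade tree to Newick
#'
#' Writes Newick with an explicit `#<int>` tag on every non-background branch
#' (placed before the branch length), so the output re-parses to the same
#' partition assignment whether or not label propagation is enabled.
#'
#' @param tree A [clade_tree()].
#' @param file Optional path; when empty the string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_tree <- function(tree, file = "", digits = 12) {
  stopifnot(inherits(tree, "clade_tree"))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (ntip == 1L) {
    tag <- if (tree$edge_partition[1] > 0) paste0("#", tree$edge_partition[1]) else ""
    out <- sprintf("%s%s:%s;", phy$tip.label[1], tag,
                   format(phy$edge.length[1], digits = digits))
  } else {
    nnode <- phy$Nnode
    if (is.null(phy$node.label)) phy$node.label <- rep("", nnode)
    for (e in seq_len(nrow(phy$edge))) {
      k <- tree$edge_partition[e]
      if (k > 0L) {
        child <- phy$edge[e, 2L]
        if (child <= ntip) {
          phy$tip.label[child] <- paste0(phy$tip.label[child], "#", k)
        } else {
          phy$node.label[child - ntip] <- paste0(phy$node.label[child - ntip], "#", k)
        }
      }
    }
    if (!any(nzchar(phy$node.label))) phy$node.label <- NULL
    out <- ape::write.tree(phy, digits = digits)
  }
  if (nzchar(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# Edge indices whose partition equals `partition`.
foreground_edges <- function(tree, partition = 1L) {
  which(tree$edge_partition == partition)
}

# All descendant node ids of `node` (excluding it), via the edge matrix.
.descendants <- function(phylo, node) {
  edge <- phylo$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    kids <- edge[edge[, 1L] %in% stack, 2L]
    out <- c(out, kids)
    stack <- kids
  }
  out
}
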