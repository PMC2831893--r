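# Static codon bookkeeping shared by the model, simulator and parsimony code:
# sense-codon list, per-codon nucleotide decomposition, and the set of
# single-nucleotide neighbour pairs with transition / synonymous flags.
codon_tables <- function() {
  if (!is.null(.retroclade_cache$tables)) {
    return(.retroclade_cache$tables)
  }
  code <- genetic_code()
  sense <- code$sense_codons
  n <- length(sense)
  nt <- c("A", "C", "G", "T")
  cmat <- t(vapply(strsplit(sense, ""), identity, character(3)))  # 61 x 3 chars
  cint <- matrix(match(cmat, nt), n, 3)                           # 61 x 3 in 1..4
  aa <- unname(code$table[sense])
  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  pi_idx <- pj_idx <- pos <- integer(0)
  ts <- syn <- logical(0)
  from_nt <- to_nt <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- which(cmat[i, ] != cmat[j, ])
      if (length(d) == 1L) {
        pi_idx <- c(pi_idx, i); pj_idx <- c(pj_idx, j); pos <- c(pos, d)
        ts <- c(ts, is_transition(cmat[i, d], cmat[j, d]))
        syn <- c(syn, aa[i] == aa[j])
        from_nt <- c(from_nt, cmat[i, d]); to_nt <- c(to_nt, cmat[j, d])
      }
    }
  }
  # Per-codon neighbour lists for the event-level simulator.
  nbr <- vector("list", n)
  for (k in seq_len(n)) nbr[[k]] <- list(j = integer(0), pos = integer(0),
                                         to = character(0))
  add <- function(a, b, p, tochar) {
    nbr[[a]]$j <<- c(nbr[[a]]$j, b)
    nbr[[a]]$pos <<- c(nbr[[a]]$pos, p)
    nbr[[a]]$to <<- c(nbr[[a]]$to, tochar)
  }
  for (k in seq_along(pi_idx)) {
    add(pi_idx[k], pj_idx[k], pos[k], to_nt[k])
    add(pj_idx[k], pi_idx[k], pos[k], from_nt[k])
  }
  tables <- list(sense = sense, aa = aa, codon_chars = cmat, codon_ints = cint,
                 pairs = data.frame(i = pi_idx, j = pj_idx, pos = pos,
                                    transition = ts, synonymous = syn,
                                    from_nt = from_nt, to_nt = to_nt),
                 neighbours = nbr)
  .retroclade_cache$tables <- tables
  tables
}

#' Codon substitution model parameters
#'
#' Bundles the parameters of the reversible codon substitution model:
#' transition/transversion rate ratio `kappa`, one nonsynonymous/synonymous
#' rate ratio `omega` per branch partition, and the 61 sense-codon stationary
#' frequencies `pi` (ordered as [genetic_code()]`$sense_codons`).
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Numeric vector of omega values, one per partition id
#'   `0..K-1` in order (a single value for the one-ratio model).
#' @param pi Stationary sense-codon frequencies, length 61, summing to 1.
#' @return Object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega, pi) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa), kappa > 0)
  omega <- as.numeric(omega)
  if (length(omega) < 1L || any(!is.finite(omega)) || any(omega < 0)) {
    stop("every omega must be finite and >= 0")
  }
  pi <- as.numeric(pi)
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-12) {
    stop("pi must be 61 non-negative frequencies summing to 1 (within 1e-12)")
  }
  structure(list(kappa = kappa, omega = omega, pi = pi),
            class = "codon_model_params")
}

#' @export
print.codon_model_params <- function(x, ...) {
  cat(sprintf("<codon_model_params> kappa = %.4g; omega = %s\n", x$kappa,
              paste(sprintf("%.4g", x$omega), collapse = ", ")))
  invisible(x)
}

#' Positional-nucleotide (F3x4) codon frequencies
#'
#' Estimates sense-codon stationary frequencies from the empirical nucleotide
#' composition at the three codon positions: the frequency of codon
#' `n1 n2 n3` is proportional to `f1(n1) f2(n2) f3(n3)`, renormalised over the
#' 61 sense codons. Counting runs over all taxa and all retained columns.
#' A positional frequency of exactly zero zeroes every codon containing that
#' base at that position; such codons are reported via the `zero_codons`
#' attribute (and a warning), since they make those states unreachable.
#'
#' @param aln A filtered codon-mode [codon_alignment()].
#' @param model `"F3x4"` (positional products, the default) or `"F61"`
#'   (empirical codon proportions with no smoothing).
#' @return Numeric vector of 61 frequencies summing to 1, ordered as
#'   [genetic_code()]`$sense_codons`.
#' @export
f3x4_frequencies <- function(aln, model = c("F3x4", "F61")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$mode != "codon") stop("codon-mode alignment required")
  if (aln$n_sites < 1L) stop("empty alignment")
  tb <- codon_tables()
  cods <- as.vector(aln$columns)
  idx <- match(cods, tb$sense)
  if (anyNA(idx)) {
    stop("alignment contains non-sense-codon states; ",
         "run filter_codon_columns() first")
  }
  if (model == "F61") {
    cnt <- tabulate(idx, nbins = 61L)
    pi <- cnt / sum(cnt)
  } else {
    nt <- c("A", "C", "G", "T")
    fpos <- matrix(0, 3, 4, dimnames = list(NULL, nt))
    for (p in 1:3) {
      cnt <- tabulate(tb$codon_ints[idx, p], nbins = 4L)
      fpos[p, ] <- cnt / sum(cnt)
    }
    pi <- fpos[1, tb$codon_ints[, 1]] *
      fpos[2, tb$codon_ints[, 2]] *
      fpos[3, tb$codon_ints[, 3]]
    pi <- unname(pi / sum(pi))
  }
  zero <- tb$sense[pi == 0]
  if (length(zero)) {
    warning("zero stationary frequency for sense codon(s): ",
            paste(zero, collapse = ", "))
    attr(pi, "zero_codons") <- zero
  }
  pi
}

#' Build the instantaneous codon rate matrix
#'
#' Constructs the 61x61 generator of the reversible codon substitution model
#' for one branch partition. Codon pairs differing at more than one nucleotide
#' have rate zero; for single-nucleotide neighbours the rate to codon `j` is
#' proportional to `pi_j`, multiplied by `kappa` when the nucleotide change is
#' a transition and by the partition's `omega` when the change is
#' nonsynonymous. The matrix is rescaled so that the expected number of
#' substitutions per codon per unit time at stationarity is one, i.e. branch
#' lengths are expected substitutions per codon under that partition's model.
#'
#' @param params A [codon_model_params()].
#' @param partition Partition id (0-based) selecting the omega.
#' @return Object of class `codon_rate_matrix`: list with `Q` (scaled
#'   generator), `pi`, `scale` (the pre-scaling substitution rate), `kappa`,
#'   `omega`.
#' @export
build_rate_matrix <- function(params, partition = 0L) {
  stopifnot(inherits(params, "codon_model_params"))
  k <- as.integer(partition)
  if (k < 0L || k >= length(params$omega)) {
    stop("unknown partition ", partition, " (model has ",
         length(params$omega), ")")
  }
  omega <- params$omega[k + 1L]
  tb <- codon_tables()
  p <- tb$pairs
  fac <- ifelse(p$transition, params$kappa, 1) * ifelse(p$synonymous, 1, omega)
  Q <- matrix(0, 61, 61, dimnames = list(tb$sense, tb$sense))
  Q[cbind(p$i, p$j)] <- params$pi[p$j] * fac
  Q[cbind(p$j, p$i)] <- params$pi[p$i] * fac
  diag(Q) <- -rowSums(Q)
  scale <- -sum(params$pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (total rate is zero)")
  structure(list(Q = Q / scale, pi = params$pi, scale = scale,
                 kappa = params$kappa, omega = omega),
            class = "codon_rate_matrix")
}

# Symmetrized eigendecomposition of a scaled generator; reversibility makes
# S = D^{1/2} Q D^{-1/2} symmetric with a real spectrum. Cached on the object.
.rate_eigen <- function(rm) {
  if (!is.null(rm$eig)) return(rm$eig)
  sq <- sqrt(rm$pi)
  ok <- sq > 0
  S <- rm$Q * (sq %o% ifelse(ok, 1 / pmax(sq, .Machine$double.xmin), 0))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sqrtpi = sq)
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' Computes the codon transition probability matrix over a branch of length
#' `t` (expected substitutions per codon) by eigendecomposition of the
#' pi^(1/2)-symmetrized generator, which is exact for the reversible model.
#'
#' @param rate_matrix A [build_rate_matrix()] result.
#' @param t Branch length, finite and >= 0.
#' @return 61x61 row-stochastic matrix.
#' @export
transition_probabilities <- function(rate_matrix, t) {
  stopifnot(inherits(rate_matrix, "codon_rate_matrix"),
            is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("negative branch length")
  e <- .rate_eigen(rate_matrix)
  inv <- ifelse(e$sqrtpi > 0, 1 / e$sqrtpi, 0)
  A <- e$U %*% (exp(e$lambda * t) * t(e$U))
  P <- (inv %o% e$sqrtpi) * A
  P[P < 0] <- 0
  P / rowSums(P)
}
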