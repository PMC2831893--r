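.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' In-silico PCR
#'
#' Predicts the amplicon a primer pair produces on a linear template. The
#' forward primer must match the plus strand at a unique position and the
#' reverse primer's reverse complement must match uniquely downstream of it;
#' the amplicon is primer-inclusive. Mismatches are opt-in and never allowed
#' in the 3'-terminal 3 nucleotides of either primer.
#'
#' @param template Template sequence (character) or a named list/character
#'   with `id` and `seq`.
#' @param fwd,rev Primer sequences, 5'->3', at least 15 nt.
#' @param max_mismatch Mismatches tolerated per primer (outside the 3' end).
#' @return Object of class `amplicon`: list with `template_id`, `start`,
#'   `end` (0-based half-open, primer-inclusive), `length`, `strand`, `sequence`.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0L) {
  if (is.list(template)) {
    id <- template$id %||% "template"
    seq <- template$seq
  } else {
    id <- names(template) %||% "template"
    seq <- unname(template)
  }
  seq <- .norm_nt(seq)
  fwd <- .norm_nt(fwd); rev <- .norm_nt(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 nt")
  subj <- Biostrings::DNAString(seq)

  find_sites <- function(pattern, three_prime_end) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = max_mismatch)
    if (max_mismatch > 0L && length(m)) {
      # The 3'-terminal 3 nt must pair exactly for extension.
      keep <- vapply(seq_along(m), function(i) {
        s <- as.character(m[[i]])
        if (three_prime_end == "right") {
          substr(s, nchar(s) - 2L, nchar(s)) ==
            substr(pattern, nchar(pattern) - 2L, nchar(pattern))
        } else {
          substr(s, 1L, 3L) == substr(pattern, 1L, 3L)
        }
      }, logical(1))
      m <- m[keep]
    }
    m
  }
  fm <- find_sites(fwd, "right")
  if (length(fm) == 0L) stop("no forward primer match")
  if (length(fm) > 1L) stop("ambiguous product: ", length(fm),
                            " forward primer matches")
  rm_ <- find_sites(.revcomp(rev), "left")
  if (length(rm_) == 0L) stop("no reverse primer match")
  if (length(rm_) > 1L) stop("ambiguous product: ", length(rm_),
                             " reverse primer matches")
  a <- Biostrings::start(fm)[1] - 1L          # 0-based amplicon start
  b <- Biostrings::end(rm_)[1]                # 0-based half-open end
  if (b - nchar(rev) < a + nchar(fwd)) {
    stop("reverse primer site upstream of forward primer site")
  }
  structure(
    list(template_id = id, start = a, end = b, length = b - a, strand = "+",
         sequence = substr(seq, a + 1L, b)),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s:%d-%d (%d bp)\n", x$template_id, x$start, x$end,
              x$length))
  invisible(x)
}

# Editable enzyme table: IUPAC recognition pattern + cut offset from the
# pattern's 5' end (top strand). Only blunt/linear behaviour is modelled.
.enzyme_table <- function() {
  data.frame(
    name = c("NlaIV", "EcoRI", "HindIII", "AluI"),
    pattern = c("GGNNCC", "GAATTC", "AAGCTT", "AGCT"),
    cut_offset = c(3L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Look up a restriction enzyme definition
#'
#' @param name Enzyme name (e.g. `"NlaIV"`), or pass a custom definition as
#'   `list(name=, pattern=, cut_offset=)` with an IUPAC pattern.
#' @return List with `name`, `pattern`, `cut_offset`.
#' @export
restriction_enzyme <- function(name) {
  if (is.list(name)) {
    stopifnot(all(c("name", "pattern", "cut_offset") %in% names(name)))
    return(name[c("name", "pattern", "cut_offset")])
  }
  tab <- .enzyme_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown enzyme '", name, "'; supply list(name, pattern, cut_offset)")
  as.list(tab[i, ])
}

#' In-silico restriction digest
#'
#' Finds every (possibly overlapping) occurrence of an enzyme's IUPAC
#' recognition pattern on a linear sequence and returns the cut positions and
#' resulting fragment lengths. Fragment lengths always sum to the input
#' length.
#'
#' @param seq Sequence to digest (character).
#' @param enzyme An enzyme name or definition (see [restriction_enzyme()]).
#' @return Object of class `digest_result`: list with `enzyme`, `pattern`,
#'   `cut_positions` (0-based, strictly increasing), `fragment_lengths`
#'   (sorted multiset), `n_sites`.
#' @export
digest_sequence <- function(seq, enzyme = "NlaIV") {
  enz <- restriction_enzyme(enzyme)
  seq <- .norm_nt(seq)
  if (grepl("[^ACGTRYSWKMBDHVN]", enz$pattern)) {
    stop("malformed IUPAC pattern '", enz$pattern, "'")
  }
  m <- Biostrings::matchPattern(enz$pattern, Biostrings::DNAString(seq),
                                fixed = FALSE)
  cuts <- sort(unique(Biostrings::start(m) - 1L + enz$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < nchar(seq)]
  frags <- diff(c(0L, cuts, nchar(seq)))
  structure(
    list(enzyme = enz$name, pattern = enz$pattern,
         cut_positions = cuts, fragment_lengths = sort(frags),
         n_sites = length(m)),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s (%s): %d cut(s); fragments: %s\n",
              x$enzyme, x$pattern, length(x$cut_positions),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Detect a target-site duplication around an insertion
#'
#' Searches for the longest direct repeat whose 5' copy ends exactly at the
#' insert's 5' boundary and whose 3' copy begins exactly at its 3' boundary
#' -- the geometry produced by target-primed reverse transcription. Copies may
#' differ by at most `max_mismatch` bases; a call shorter than `min_len` is
#' reported as no TSD.
#'
#' @param locus Locus sequence (character).
#' @param insert_interval 0-based half-open interval of the insert proper.
#' @param max_len Longest repeat length considered.
#' @param max_mismatch Mismatch budget between the two copies.
#' @param min_len Minimum reportable repeat length.
#' @return Object of class `tsd_call` (list with `seq`, `interval5`,
#'   `interval3`, `length`, `mismatches`, `en_site` or `NA`), or `NULL` when
#'   no repeat of at least `min_len` exists.
#' @export
find_tsd <- function(locus, insert_interval, max_len = 30L, max_mismatch = 0L,
                     min_len = 6L) {
  locus <- .norm_nt(locus)
  a <- insert_interval[1]; b <- insert_interval[2]
  n <- nchar(locus)
  if (a < 0L || b > n || a >= b) stop("insert interval outside locus")
  max_len <- min(max_len, a, n - b)
  best_k <- 0L; best_mm <- 0L
  left_all <- strsplit(substr(locus, a - max_len + 1L, a), "")[[1]]
  right_all <- strsplit(substr(locus, b + 1L, b + max_len), "")[[1]]
  for (k in seq_len(max_len)) {
    # 5' window [a-k, a) read left-to-right vs 3' window [b, b+k).
    mm <- sum(left_all[seq(max_len - k + 1L, max_len)] != right_all[seq_len(k)])
    if (mm <= max_mismatch) {
      best_k <- k; best_mm <- mm
    }
  }
  if (best_k < min_len) return(NULL)
  tsd5 <- c(a - best_k, a)
  # The L1 endonuclease nick sits immediately 5' of the duplicated target.
  en <- scan_en_sites(locus)
  en_here <- en$position[en$strand == "+" & en$position == tsd5[1]]
  structure(
    list(seq = substr(locus, a - best_k + 1L, a),
         interval5 = tsd5, interval3 = c(b, b + best_k),
         length = best_k, mismatches = best_mm,
         en_site = if (length(en_here)) en_here[1] else NA_integer_),
    class = "tsd_call"
  )
}

#' Scan for L1 endonuclease target sites
#'
#' Finds every occurrence of the L1 endonuclease cleavage motif 5'-TTTT/A-3'
#' on both strands and reports the 0-based cleavage point in plus-strand
#' coordinates (the number of bases 5' of the nick). Sites matching the
#' extended preferred motif TTTT/AA are flagged.
#'
#' @param seq Sequence to scan.
#' @return Data frame with columns `position` (0-based cleavage point),
#'   `strand` (`"+"`/`"-"`), `extended` (TTTT/AA variant).
#' @export
scan_en_sites <- function(seq) {
  seq <- .norm_nt(seq)
  n <- nchar(seq)
  hit_one_strand <- function(s) {
    out <- integer(0); ext <- logical(0)
    m <- gregexpr("(?=TTTTA)", s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      out <- as.integer(m) - 1L + 4L   # cut between TTTT and A
      ext <- vapply(as.integer(m), function(i) {
        substr(s, i + 5L, i + 5L) == "A"
      }, logical(1))
    }
    list(pos = out, ext = ext)
  }
  fwd <- hit_one_strand(seq)
  rev <- hit_one_strand(.revcomp(seq))
  # Reverse-strand cut at rc-coordinate p maps to plus coordinate n - p.
  data.frame(
    position = c(fwd$pos, n - rev$pos),
    strand = rep(c("+", "-"), c(length(fwd$pos), length(rev$pos))),
    extended = c(fwd$ext, rev$ext)
  )[order(c(fwd$pos, n - rev$pos)), , drop = FALSE]
}

#' Rap1 functional motif map
#'
#' 1-based residue intervals of the conserved guanine-nucleotide-binding
#' motifs (G1 = P-loop/Walker A, G2-G4) and the effector domain of Ras-family
#' Rap1 GTPases: residues 20-45, split into the general recognition motif
#' (32-40) and the flanking specificity regions (20-31, 41-45).
#'
#' @return Data frame with columns `motif`, `start`, `end`.
#' @export
rap1_motifs <- function() {
  data.frame(
    motif = c("G1", "G2", "G3", "G4",
              "effector_recognition", "effector_specificity",
              "effector_specificity"),
    start = c(10L, 28L, 57L, 116L, 32L, 20L, 41L),
    end = c(17L, 40L, 60L, 119L, 40L, 31L, 45L),
    stringsAsFactors = FALSE
  )
}

#' Amino-acid differences between a parent gene and its retrocopy
#'
#' Compares two equal-length proteins (or ORFs, which are translated first)
#' position by position and reports each substitution in `from-position-to`
#' notation together with the functional motifs it falls in (see
#' [rap1_motifs()]). Unequal lengths are an error: retrocopy ORFs are
#' unspliced full-length copies, so a length difference signals an upstream
#' problem that must be resolved by explicit alignment, not silently.
#'
#' @param parent_orf,retro_orf Protein strings, or nucleotide ORFs (detected
#'   by alphabet, or forced via `type`).
#' @param type `"auto"`, `"nucleotide"` or `"protein"`.
#' @param motifs Motif map data frame (`motif`, `start`, `end`).
#' @return Object of class `protein_diff`: data frame with `position`
#'   (1-based), `from`, `to`, `notation`, `motif` (comma-joined labels or
#'   `"none"`).
#' @export
protein_diff <- function(parent_orf, retro_orf, type = c("auto", "nucleotide", "protein"),
                         motifs = rap1_motifs()) {
  type <- match.arg(type)
  as_protein <- function(x) {
    if (type == "protein") return(toupper(x))
    if (type == "nucleotide") return(translate_orf(x))
    xx <- .norm_nt(x)
    if (!grepl("[^ACGT]", xx) && nchar(xx) %% 3L == 0L) translate_orf(xx)
    else toupper(x)
  }
  p <- as_protein(parent_orf)
  r <- as_protein(retro_orf)
  if (nchar(p) != nchar(r)) {
    stop("protein lengths differ (", nchar(p), " vs ", nchar(r),
         "); align explicitly before comparing")
  }
  pv <- strsplit(p, "")[[1]]
  rv <- strsplit(r, "")[[1]]
  idx <- which(pv != rv)
  annot <- vapply(idx, function(i) {
    hit <- motifs$motif[motifs$start <= i & i <= motifs$end]
    if (length(hit)) paste(unique(hit), collapse = ",") else "none"
  }, character(1))
  out <- data.frame(
    position = idx, from = pv[idx], to = rv[idx],
    notation = paste0(pv[idx], idx, rv[idx]),
    motif = annot,
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_diff", "data.frame")
  out
}
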