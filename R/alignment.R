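#' Construct a codon alignment object
#'
#' A codon alignment is stored as a character matrix of codon (or single
#' nucleotide, in nucleotide mode) columns, rows named by taxa. `source_mask`
#' tracks which original columns survive filtering so downstream coordinates
#' can always be mapped back to the input alignment.
#'
#' @param seqs Named character vector of equal-length aligned sequences, or a
#'   character matrix of codon states (rows = taxa).
#' @param mode `"codon"` (columns are 3-letter codons) or `"nucleotide"`.
#' @return Object of class `codon_alignment` with elements `taxa`, `columns`
#'   (character matrix, taxa x sites), `n_sites`, `source_mask`, `mode`.
#' @export
codon_alignment <- function(seqs, mode = c("codon", "nucleotide")) {
  mode <- match.arg(mode)
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(rownames(mat))) stop("matrix input must have row names (taxa)")
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named")
    }
    seqs <- vapply(seqs, .norm_nt, character(1))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    w <- if (mode == "codon") 3L else 1L
    if (lens[1] %% w != 0L) {
      stop("alignment length ", lens[1], " not divisible by 3 in codon mode")
    }
    starts <- seq(1L, lens[1], w)
    mat <- t(vapply(seqs, function(s) substring(s, starts, starts + w - 1L),
                    character(length(starts))))
    if (length(starts) == 1L) {
      mat <- matrix(mat, nrow = length(seqs), ncol = 1L,
                    dimnames = list(names(seqs), NULL))
    }
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate sequence ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  structure(
    list(taxa = rownames(mat), columns = mat, n_sites = ncol(mat),
         source_mask = seq_len(ncol(mat)), mode = mode),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d %s columns\n",
              length(x$taxa), x$n_sites,
              if (x$mode == "codon") "codon" else "nucleotide"))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multiple alignment from FASTA. Sequences must all have the same
#' length; in codon mode the length must be divisible by three. Input order is
#' preserved and no filtering is applied (see [filter_codon_columns()]).
#'
#' @param path Path to a FASTA file.
#' @param mode `"codon"` or `"nucleotide"`.
#' @return A [codon_alignment()] object.
#' @export
load_alignment <- function(path, mode = c("codon", "nucleotide")) {
  mode <- match.arg(mode)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no records in '", path, "'")
  seqs <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  codon_alignment(seqs, mode = mode)
}

#' Write an alignment to FASTA
#'
#' @param aln A [codon_alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$columns, 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", aln$taxa[i]), seqs[i]), con)
  }
  invisible(path)
}

#' Drop codon columns with gaps, ambiguities or stops
#'
#' Complete-case filtering for likelihood analysis: a codon column is retained
#' only when every taxon carries one of the 61 sense codons. Columns containing
#' a gap or any non-ACGT character in any taxon are dropped. Stop codons are an
#' error by default (alignments of intact ORFs should have none) or dropped
#' with `stop_policy = "drop"`. The returned `source_mask` holds the original
#' column indices of the survivors.
#'
#' @param aln A codon-mode [codon_alignment()].
#' @param stop_policy `"error"` or `"drop"`.
#' @return A filtered `codon_alignment`.
#' @export
filter_codon_columns <- function(aln, stop_policy = c("error", "drop")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$mode != "codon") stop("filtering requires a codon-mode alignment")
  code <- genetic_code()
  m <- aln$columns
  clean <- matrix(!grepl("[^ACGT]", m), nrow = nrow(m))
  col_clean <- apply(clean, 2L, all)
  is_stop <- matrix(m %in% code$stop_codons, nrow = nrow(m))
  col_stop <- apply(is_stop, 2L, any) & col_clean
  if (any(col_stop) && stop_policy == "error") {
    stop("stop codon in alignment column(s) ",
         paste(aln$source_mask[which(col_stop)], collapse = ", "),
         " (use stop_policy = \"drop\" to discard them)")
  }
  keep <- col_clean & !col_stop
  if (!any(keep)) stop("no codon columns remain after filtering")
  out <- aln
  out$columns <- m[, keep, drop = FALSE]
  out$n_sites <- sum(keep)
  out$source_mask <- aln$source_mask[keep]
  out
}
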