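#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as a small object holding the
#' 64-entry codon -> amino-acid table (stop codons encoded as `"*"`) and the 61
#' sense codons in fixed lexicographic order (alphabet A < C < G < T). All
#' codon-indexed quantities in the package (stationary frequencies, rate
#' matrices, tip states) follow this sense-codon ordering.
#'
#' @return An object of class `genetic_code`: a list with elements `table`
#'   (named character vector of length 64), `sense_codons` (character vector of
#'   length 61), and `stop_codons` (length 3).
#' @examples
#' code <- genetic_code()
#' code$table[["ATG"]]   # "M"
#' length(code$sense_codons)
#' @export
genetic_code <- function() {
  if (!is.null(.retroclade_cache$code)) {
    return(.retroclade_cache$code)
  }
  # Standard code laid out in the classic TCAG-table order, then re-keyed.
  base2 <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLL", "SSSS", "YY**", "CC*W",   # TTx TCx TAx TGx
    "LLLL", "PPPP", "HHQQ", "RRRR",   # CTx CCx CAx CGx
    "IIIM", "TTTT", "NNKK", "SSRR",   # ATx ACx AAx AGx
    "VVVV", "AAAA", "DDEE", "GGGG"    # GTx GCx GAx GGx
  ), "")[[1]]
  codons_tcag <- as.vector(t(outer(
    as.vector(t(outer(base2, base2, paste0))), base2, paste0
  )))
  tab <- setNames(aa, codons_tcag)
  lex <- sort(names(tab))              # lexicographic A<C<G<T
  tab <- tab[lex]
  stops <- names(tab)[tab == "*"]
  stopifnot(length(tab) == 64L, length(stops) == 3L)
  code <- structure(
    list(
      table = tab,
      sense_codons = names(tab)[tab != "*"],
      stop_codons = stops
    ),
    class = "genetic_code"
  )
  .retroclade_cache$code <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code: 64 codons, 61 sense,",
      "stops:", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

# Normalise raw nucleotide input: uppercase, RNA U -> T.
.norm_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Translate an open reading frame
#'
#' Translates a nucleotide ORF into a 1-letter amino-acid string under the
#' supplied genetic code. Input is case-insensitive and `U` is read as `T`.
#' A terminal stop codon is stripped; an internal stop is an error because the
#' function is meant for intact coding sequences.
#'
#' @param seq Nucleotide string, length divisible by 3, plain A/C/G/T only.
#' @param code A [genetic_code()] object.
#' @return Single amino-acid string (1-letter residues, 1-based numbering).
#' @examples
#' translate_orf("ATGGGT")  # "MG"
#' translate_orf("ACG")     # "T"
#' @export
translate_orf <- function(seq, code = genetic_code()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- .norm_nt(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  if (nchar(s) %% 3L != 0L) stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", s)) {
    stop("sequence contains characters other than A/C/G/T (ambiguity codes ",
         "and gaps cannot be translated)")
  }
  cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- unname(code$table[cods])
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    stop("internal stop codon at codon position ", which(aa == "*")[1L])
  }
  paste(aa, collapse = "")
}
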