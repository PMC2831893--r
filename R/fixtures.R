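# ---------------------------------------------------------------------------
# Synthetic Rap1 fixture family.
#
# Real Rap1 mRNA/genomic records cannot be redistributed with the package, so
# these are SYNTHETIC stand-ins, generated deterministically in code. They
# embed the documented facts about the system -- the RT-PCR primer pair, a
# primer-inclusive 1186 bp amplicon, a single NlaIV site (GGNNCC, blunt cut
# after position 3) placed 213 bp into the amplicon of the parental mRap1A
# cDNA and synonymously destroyed in the retrocopies, the Ras-family motif
# residues (G1-G4, effector domain), the 9 amino-acid differences between the
# Rap1A and Rap1B paralog proteins, and the retrogene substitutions
# A59V (retro1, plus the synonymous T35T change), I9L/T35M/L96V (retro2) and
# G12R/K42E (hRap1B-retro). Everything else (UTRs, unconstrained residues) is
# pseudo-random with a fixed internal seed. They exercise the locus
# diagnostics end-to-end; they are NOT the GenBank records.
# ---------------------------------------------------------------------------

# Fixed codon choice per amino acid for the synthetic ORFs.
.aa_codon <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
               Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
               L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
               S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

# Remove unwanted IUPAC-pattern matches from a cDNA by minimal synonymous
# (ORF) or free (UTR) single-base edits. `keep_start` is the 0-based start of
# a match to preserve (NA = remove all); `reserved` is a logical mask of
# untouchable positions (primers, planted site, constrained codons).
.scrub_pattern <- function(cdna, pattern, keep_start, orf_start0, orf_len,
                           reserved, code = genetic_code()) {
  for (iter in 1:200) {
    hits <- Biostrings::start(Biostrings::matchPattern(
      pattern, Biostrings::DNAString(cdna), fixed = FALSE)) - 1L
    extra <- setdiff(hits, keep_start)
    if (!length(extra)) return(cdna)
    s <- extra[1]
    fixed_it <- FALSE
    for (off in c(5L, 4L, 1L, 0L)) {       # the G,G,C,C informative positions
      p <- s + off                          # 0-based coordinate of the base
      if (p < 0L || p >= nchar(cdna) || reserved[p + 1L]) next
      in_orf <- p >= orf_start0 && p < orf_start0 + orf_len
      if (in_orf) {
        ci <- (p - orf_start0) %/% 3L       # 0-based codon index
        cp <- (p - orf_start0) %% 3L + 1L   # position within codon
        cod0 <- orf_start0 + 3L * ci
        if (any(reserved[(cod0 + 1L):(cod0 + 3L)])) next
        cod <- substr(cdna, cod0 + 1L, cod0 + 3L)
        aa <- code$table[[cod]]
        alts <- code$sense_codons[code$table[code$sense_codons] == aa]
        alts <- alts[substr(alts, cp, cp) != substr(cod, cp, cp)]
        if (!length(alts)) next
        substr(cdna, cod0 + 1L, cod0 + 3L) <- alts[1]
      } else {
        cur <- substr(cdna, p + 1L, p + 1L)
        substr(cdna, p + 1L, p + 1L) <- if (cur == "A") "G" else "A"
      }
      still <- Biostrings::start(Biostrings::matchPattern(
        pattern, Biostrings::DNAString(cdna), fixed = FALSE)) - 1L
      if (!(s %in% still)) {
        fixed_it <- TRUE
        break
      }
    }
    if (!fixed_it) stop("could not scrub pattern occurrence at ", s)
  }
  stop("pattern scrub did not converge")
}

#' Synthetic Rap1 sequence fixtures
#'
#' Deterministically generated stand-ins for the Rap1 cDNA family used by the
#' locus diagnostics: the parental mouse Rap1A cDNA, its two retrocopies, the
#' human Rap1B paralog and its retrocopy, together with the RT-PCR primer
#' pair. These are synthetic sequences (see source comments): they reproduce
#' the documented assay geometry -- a 1186 bp primer-inclusive amplicon whose
#' single NlaIV site cuts it into 213 + 973 bp fragments for the parental
#' cDNA only -- and the documented protein differences (9 residues between
#' Rap1A and Rap1B; A59V in retro1; I9L, T35M, L96V in retro2; G12R, K42E in
#' the Rap1B retrocopy), with all remaining positions pseudo-random under a
#' fixed seed. They are not database records.
#'
#' @return List with `cdnas` and `proteins` (named character vectors),
#'   `orfs` (named character vector of the coding sequences incl. stop),
#'   `primers` (list `fwd`, `rev`), `enzyme` (`"NlaIV"`), and
#'   `amplicon_geometry` (list: amplicon start offset, length, cut offset).
#' @export
rap1_synthetic_fixtures <- function() {
  if (!is.null(.retroclade_cache$rap1_fixtures)) {
    return(.retroclade_cache$rap1_fixtures)
  }
  code <- genetic_code()
  n_res <- 184L
  aa20 <- names(.aa_codon)
  fixed_res <- c(
    `1` = "M",
    `9` = "I", `10` = "G", `12` = "G", `15` = "G", `16` = "K", `17` = "S",
    `28` = "F", `29` = "V", `32` = "Y", `34` = "P", `35` = "T", `38` = "D",
    `40` = "Y", `42` = "K",
    `51` = "G", `52` = "T",            # hosts the discriminating NlaIV site
    `57` = "D", `59` = "A", `60` = "G",
    `96` = "L",
    `116` = "N", `117` = "K", `119` = "D"
  )
  fixed_cod <- c(
    `9` = "ATA", `12` = "GGA", `35` = "ACG", `42` = "AAG",
    `51` = "GGA", `52` = "ACC", `59` = "GCG", `96` = "CTG"
  )
  fwd <- "GCGGGATTGTCAATATTTAAAC"
  rev <- "GCCATAGAAATCAGTTATCCC"

  fx <- with_seed(1202L, {
    prot_a <- sample(aa20, n_res, replace = TRUE)
    prot_a[as.integer(names(fixed_res))] <- fixed_res
    # Paralog protein: 9 differences, mostly C-terminal, off the motif map.
    diff_pos <- c(104L, 130L, 139L, 146L, 153L, 161L, 169L, 176L, 182L)
    prot_b <- prot_a
    for (i in diff_pos) {
      prot_b[i] <- sample(setdiff(aa20, prot_a[i]), 1L)
    }
    codons_for <- function(prot) {
      cods <- unname(.aa_codon[prot])
      fixed_ok <- prot[as.integer(names(fixed_cod))] ==
        code$table[unname(fixed_cod)]
      cods[as.integer(names(fixed_cod))[fixed_ok]] <- fixed_cod[fixed_ok]
      cods
    }
    orf_a <- paste0(paste(codons_for(prot_a), collapse = ""), "TAA")
    orf_b <- paste0(paste(codons_for(prot_b), collapse = ""), "TAA")
    rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
    # mRap1A-style cDNA: the amplicon is primer-inclusive and spans the ORF
    # plus a long stretch of 3'UTR.
    amp_len <- 1186L
    pre <- 30L                 # bases 5' of the forward primer site
    orf_amp_off <- 60L         # ORF offset within the amplicon
    utr5_fill <- orf_amp_off - nchar(fwd)
    utr3_len <- amp_len - orf_amp_off - nchar(orf_a) - nchar(rev)
    cdna_a <- paste0(rand_nt(pre), fwd, rand_nt(utr5_fill), orf_a,
                     rand_nt(utr3_len), .revcomp(rev), rand_nt(30L))
    # Rap1B-style cDNA: no amplicon geometry needed, short UTRs.
    cdna_b <- paste0(rand_nt(20L), orf_b, rand_nt(40L))
    list(prot_a = prot_a, prot_b = prot_b, orf_a = orf_a, orf_b = orf_b,
         cdna_a = cdna_a, cdna_b = cdna_b, amp_len = amp_len, pre = pre,
         orf_amp_off = orf_amp_off)
  })

  orf_start0 <- fx$pre + fx$orf_amp_off
  orf_len <- nchar(fx$orf_a)
  n_a <- nchar(fx$cdna_a)
  reserved <- logical(n_a)
  reserved[(fx$pre + 1L):(fx$pre + nchar(fwd))] <- TRUE          # fwd primer
  rev_at <- fx$pre + fx$amp_len - nchar(rev)
  reserved[(rev_at + 1L):(rev_at + nchar(rev))] <- TRUE          # rev primer
  for (ci in as.integer(names(fixed_cod))) {                     # key codons
    k <- orf_start0 + 3L * (ci - 1L)
    reserved[(k + 1L):(k + 3L)] <- TRUE
  }
  planted <- orf_start0 + 3L * (51L - 1L)   # 0-based start of codon 51
  stopifnot(substr(fx$cdna_a, planted + 1L, planted + 6L) == "GGAACC",
            planted - fx$pre + 3L == 213L)  # cut 213 bp into the amplicon
  cdna_a <- .scrub_pattern(fx$cdna_a, "GGNNCC", keep_start = planted,
                           orf_start0 = orf_start0, orf_len = orf_len,
                           reserved = reserved)

  edit_codon <- function(cdna, res_idx, new_codon, orf0 = orf_start0) {
    k <- orf0 + 3L * (res_idx - 1L)
    substr(cdna, k + 1L, k + 3L) <- new_codon
    cdna
  }
  # Retrocopies of the parental cDNA. Both lose the NlaIV site through the
  # synonymous codon-52 change; retro1 additionally carries the synonymous
  # T35T change (ACG -> ACA) and the A59V replacement, retro2 the I9L, T35M,
  # L96V replacements.
  retro_common <- edit_codon(cdna_a, 52L, "ACT")
  cdna_r1 <- edit_codon(edit_codon(retro_common, 35L, "ACA"), 59L, "GTG")
  cdna_r2 <- edit_codon(edit_codon(edit_codon(retro_common, 9L, "CTA"),
                                   35L, "ATG"), 96L, "GTG")
  res_r1 <- reserved
  res_r1[(orf_start0 + 3L * 50L + 1L):(orf_start0 + 3L * 52L)] <- TRUE
  cdna_r1 <- .scrub_pattern(cdna_r1, "GGNNCC", keep_start = integer(0),
                            orf_start0, orf_len, res_r1)
  cdna_r2 <- .scrub_pattern(cdna_r2, "GGNNCC", keep_start = integer(0),
                            orf_start0, orf_len, res_r1)

  # Rap1B retrocopy: G12R and K42E on the paralog ORF.
  orf0_b <- 20L
  cdna_bret <- edit_codon(edit_codon(fx$cdna_b, 12L, "AGA", orf0 = orf0_b),
                          42L, "GAG", orf0 = orf0_b)

  extract_orf <- function(cdna, orf0, len = orf_len) {
    substr(cdna, orf0 + 1L, orf0 + len)
  }
  orfs <- c(
    mRap1A = extract_orf(cdna_a, orf_start0),
    mRap1A_retro1 = extract_orf(cdna_r1, orf_start0),
    mRap1A_retro2 = extract_orf(cdna_r2, orf_start0),
    hRap1B = extract_orf(fx$cdna_b, orf0_b),
    hRap1B_retro = extract_orf(cdna_bret, orf0_b)
  )
  out <- list(
    cdnas = c(mRap1A = cdna_a, mRap1A_retro1 = cdna_r1,
              mRap1A_retro2 = cdna_r2, hRap1B = fx$cdna_b,
              hRap1B_retro = cdna_bret),
    orfs = orfs,
    proteins = vapply(orfs, translate_orf, character(1)),
    primers = list(fwd = fwd, rev = rev),
    enzyme = "NlaIV",
    amplicon_geometry = list(start = fx$pre, length = fx$amp_len,
                             cut_at = 213L),
    synthetic = TRUE
  )
  .retroclade_cache$rap1_fixtures <- out
  out
}

#' Demonstration species tree for the retrogene analysis
#'
#' A 7-species mammalian phylogeny (human, chimp, macaque, cow, dog, rat,
#' mouse) with, optionally, a two-retrocopy clade grafted onto the mouse
#' lineage and labelled as foreground partition 1. Two basal arrangements are
#' available: `"established"` places rodents with primates,
#' `"alternative"` places rodents with the cow/dog clade; omega estimates
#' should be insensitive to this choice. Branch lengths (expected
#' substitutions per codon) are package defaults chosen to reflect a strongly
#' conserved mammalian gene; they are fixture values, not estimates.
#'
#' @param topology `"established"` or `"alternative"` basal arrangement.
#' @param retro Include the retrogene clade (partition 1)?
#' @return A [clade_tree()].
#' @export
rap1_species_tree <- function(topology = c("established", "alternative"),
                              retro = TRUE) {
  topology <- match.arg(topology)
  rodents <- if (retro) {
    "((mouse:0.04,(retro1:0.025,retro2:0.025)#1:0.02):0.05,rat:0.08):0.045"
  } else {
    "(mouse:0.09,rat:0.08):0.045"
  }
  primates <- "((human:0.01,chimp:0.01):0.015,macaca:0.03):0.05"
  lauras <- "(cow:0.08,dog:0.08):0.06"
  txt <- if (topology == "established") {
    sprintf("((%s,%s):0.02,%s);", rodents, primates, lauras)
  } else {
    sprintf("((%s,%s):0.02,%s);", rodents, lauras, primates)
  }
  load_tree(txt, propagate = TRUE)
}

#' Four-taxon codon alignment of the retrogene diagnostic sites
#'
#' A small codon alignment of the four informative codon sites (9, 35, 59,
#' 96) for the mouse Rap1A lineage: an outgroup ortholog, the parental mouse
#' gene, and the two retrocopies, with the retrocopy states implied by the
#' substitutions A59V + the synonymous T35T change (retro1) and I9L, T35M,
#' L96V (retro2). Intended for the parsimony-reconstruction worked example;
#' the tracked-site numbering is preserved via the `sites` attribute.
#'
#' @return List with `alignment` (a [codon_alignment()] of the 4 columns),
#'   `tree` (a rooted 4-taxon [clade_tree()]), and `sites` (the original
#'   codon numbers).
#' @export
rap1_retro_site_alignment <- function() {
  seqs <- c(
    rat    = paste0("ATA", "ACG", "GCG", "CTG"),
    mouse  = paste0("ATA", "ACG", "GCG", "CTG"),
    retro1 = paste0("ATA", "ACA", "GTG", "CTG"),
    retro2 = paste0("CTA", "ATG", "GCG", "GTG")
  )
  tree <- load_tree(paste0("(((retro1:0.01,retro2:0.01)#1:0.01,",
                           "mouse:0.02):0.02,rat:0.04);"))
  list(alignment = codon_alignment(seqs), tree = tree,
       sites = c(9L, 35L, 59L, 96L))
}

#' Compact two-partition tree for calibration studies
#'
#' A six-taxon tree with a two-tip foreground clade (partition 1), used by
#' the likelihood-ratio-test calibration studies where hundreds of model
#' fits are required and a small tree keeps each fit cheap.
#'
#' @return A [clade_tree()].
#' @export
calibration_tree <- function() {
  load_tree(paste0("(((bg1:0.05,bg2:0.05):0.05,",
                   "(fg1:0.03,fg2:0.03)#1:0.04):0.05,",
                   "(bg3:0.08,bg4:0.08):0.05);"))
}
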