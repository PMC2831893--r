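fx <- rap1_synthetic_fixtures()

test_that("the diagnostic RT-PCR amplicon and NlaIV digest reproduce the assay geometry", {
  amp <- in_silico_pcr(fx$cdnas[["mRap1A"]], fx$primers$fwd, fx$primers$rev)
  expect_equal(amp$length, 1186L)
  expect_equal(amp$end - amp$start, amp$length)
  dg <- digest_sequence(amp$sequence, "NlaIV")
  expect_equal(dg$fragment_lengths, c(213L, 973L))
  expect_equal(sum(dg$fragment_lengths), amp$length)
  # the site is absent from both retrocopy amplicons: single uncut fragment
  for (r in c("mRap1A_retro1", "mRap1A_retro2")) {
    a <- in_silico_pcr(fx$cdnas[[r]], fx$primers$fwd, fx$primers$rev)
    expect_equal(a$length, 1186L)
    expect_equal(digest_sequence(a$sequence, "NlaIV")$fragment_lengths, 1186L)
  }
})

test_that("PCR errors are explicit and matching is unique", {
  expect_error(in_silico_pcr(paste(rep("ACGT", 20), collapse = ""),
                             fx$primers$fwd, fx$primers$rev),
               "no forward")
  tmpl <- paste0(fx$primers$fwd, paste(rep("A", 40), collapse = ""))
  expect_error(in_silico_pcr(tmpl, fx$primers$fwd, fx$primers$rev),
               "no reverse")
  # reverse site upstream of forward site
  bad <- paste0(retroclade:::.revcomp(fx$primers$rev),
                paste(rep("C", 30), collapse = ""), fx$primers$fwd)
  expect_error(in_silico_pcr(bad, fx$primers$fwd, fx$primers$rev), "upstream")
  # duplicated forward site is ambiguous
  dup <- paste0(fx$primers$fwd, "ACGTACGT", fx$primers$fwd,
                paste(rep("T", 30), collapse = ""),
                retroclade:::.revcomp(fx$primers$rev))
  expect_error(in_silico_pcr(dup, fx$primers$fwd, fx$primers$rev), "ambiguous")
})

test_that("planted primer sites are recovered at their coordinates", {
  set.seed(12)
  nt <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    fwd <- paste(sample(nt, 20, TRUE), collapse = "")
    rev <- paste(sample(nt, 20, TRUE), collapse = "")
    gap <- sample(50:300, 1)
    pre <- sample(10:60, 1)
    tmpl <- paste0(paste(sample(nt, pre, TRUE), collapse = ""), fwd,
                   paste(sample(nt, gap, TRUE), collapse = ""),
                   retroclade:::.revcomp(rev),
                   paste(sample(nt, 25, TRUE), collapse = ""))
    amp <- tryCatch(in_silico_pcr(tmpl, fwd, rev), error = function(e) NULL)
    if (is.null(amp)) next   # rare chance second match in random flanks
    expect_equal(amp$start, pre)
    expect_equal(amp$length, 40 + gap)
    # idempotence: amplifying the amplicon returns it whole
    again <- in_silico_pcr(amp$sequence, fwd, rev)
    expect_identical(again$sequence, amp$sequence)
  }
})

test_that("digestion matches a sliding-window IUPAC oracle on random sequence", {
  set.seed(8)
  for (rep in 1:6) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    dg <- digest_sequence(seq, "NlaIV")
    hits0 <- iupac_scan(seq, "GGNNCC") - 1L   # 0-based starts
    cuts0 <- sort(unique(hits0 + 3L))
    cuts0 <- cuts0[cuts0 > 0 & cuts0 < nchar(seq)]
    expect_identical(dg$cut_positions, cuts0)
    expect_equal(sum(dg$fragment_lengths), nchar(seq))
  }
  # overlapping recognition sites are all reported
  dg <- digest_sequence("AAGGGGCCCCAA", "NlaIV")
  expect_identical(iupac_scan("AAGGGGCCCCAA", "GGNNCC") - 1L,
                   c(2L, 3L, 4L))
  expect_equal(dg$n_sites, 3L)
  # no site: one fragment of full length
  expect_equal(digest_sequence("ATATATATAT", "NlaIV")$fragment_lengths, 10L)
  expect_error(digest_sequence("ACGT", list(name = "bad", pattern = "GGXX",
                                            cut_offset = 1L)), "malformed")
})

test_that("planted TSDs are recovered exactly with their endonuclease site", {
  for (s in 1:20) {
    k <- 8L + (s %% 9L)
    loc <- simulate_insertion_locus(70, k, insert_seq = "ATGACGTAGCATCGGATC",
                                    seed = s)
    call <- find_tsd(loc$sequence, loc$insert_interval)
    expect_false(is.null(call))
    expect_identical(call$seq, loc$tsd$seq)
    expect_equal(call$length, k)
    expect_equal(call$mismatches, 0L)
    expect_equal(call$interval5, loc$tsd$interval5)
    expect_equal(call$interval3, loc$tsd$interval3)
    expect_equal(call$en_site, loc$en_site)
  }
})

test_that("the TSD search honours the mismatch budget and interval checks", {
  loc <- simulate_insertion_locus(70, 12, insert_seq = "ATGACGTAGCAT", seed = 2)
  s <- loc$sequence
  # corrupt one base inside the 3' copy
  pos <- loc$tsd$interval3[1] + 5L
  cur <- substr(s, pos + 1, pos + 1)
  substr(s, pos + 1, pos + 1) <- if (cur == "A") "C" else "A"
  expect_null(find_tsd(s, loc$insert_interval, max_mismatch = 0L))
  call <- find_tsd(s, loc$insert_interval, max_mismatch = 1L)
  expect_equal(call$length, 12L)
  expect_equal(call$mismatches, 1L)
  expect_error(find_tsd(s, c(-1, 10)), "outside")
})

test_that("endonuclease site scanning matches a regex oracle on both strands", {
  hits <- scan_en_sites("ctcaatcctaTTTTAtgaaatccat")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 14L)   # cut between the T run and the A
  expect_identical(hits$strand, "+")
  expect_false(hits$extended)
  expect_true(scan_en_sites("GGTTTTAAGG")$extended[1])
  expect_equal(nrow(scan_en_sites("ACGCATGCATGC")), 0L)

  set.seed(3)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    out <- scan_en_sites(seq)
    fwd_oracle <- gregexpr("(?=TTTTA)", seq, perl = TRUE)[[1]]
    fwd_oracle <- if (fwd_oracle[1] == -1L) integer(0) else
      as.integer(fwd_oracle) + 3L
    expect_setequal(out$position[out$strand == "+"], fwd_oracle)
    # strand symmetry: hits on the reverse complement mirror coordinates
    rc <- retroclade:::.revcomp(seq)
    out_rc <- scan_en_sites(rc)
    n <- nchar(seq)
    expect_setequal(n - out_rc$position[out_rc$strand == "+"],
                    out$position[out$strand == "-"])
  }
})

test_that("protein differences carry the documented notations and motifs", {
  pd <- protein_diff(fx$proteins[["mRap1A"]], fx$proteins[["hRap1B"]])
  expect_equal(nrow(pd), 9L)   # paralogs differ by nine residues
  r1 <- protein_diff(fx$proteins[["mRap1A"]], fx$proteins[["mRap1A_retro1"]])
  expect_identical(r1$notation, "A59V")
  expect_match(r1$motif, "G3")
  r2 <- protein_diff(fx$proteins[["mRap1A"]], fx$proteins[["mRap1A_retro2"]])
  expect_identical(r2$notation, c("I9L", "T35M", "L96V"))
  expect_match(r2$motif[r2$notation == "T35M"], "effector_recognition")
  rb <- protein_diff(fx$proteins[["hRap1B"]], fx$proteins[["hRap1B_retro"]])
  expect_identical(rb$notation, c("G12R", "K42E"))
  expect_match(rb$motif[rb$notation == "G12R"], "G1")
  expect_match(rb$motif[rb$notation == "K42E"], "effector_specificity")
  # self-comparison and length guard
  expect_equal(nrow(protein_diff("MREYK", "MREYK", type = "protein")), 0L)
  expect_error(protein_diff("MREYK", "MREY", type = "protein"), "lengths differ")
  # nucleotide inputs are translated first
  nd <- protein_diff(fx$orfs[["mRap1A"]], fx$orfs[["mRap1A_retro1"]])
  expect_identical(nd$notation, "A59V")
})
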