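# Shared provenance block written at the top of every report.
.provenance <- function(cfg) {
  c(sprintf("# retroclade %s",
            as.character(utils::packageVersion("retroclade"))),
    sprintf("# seed: %s", cfg$seed %||% "none"),
    sprintf("# config: %s",
            paste(names(cfg), vapply(cfg, function(x) {
              paste(format(unlist(x)), collapse = "/")
            }, character(1)), sep = "=", collapse = " ")))
}

.write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_tree <- function(x, ...) {
  if (inherits(x, "clade_tree")) x else load_tree(x, ...)
}

.as_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) x else load_alignment(x)
}

#' Run the clade-model fitting stage
#'
#' End-to-end omega analysis: filter the alignment to complete sense-codon
#' columns, estimate stationary frequencies (F3x4), fit the one-ratio (M0)
#' and two-clades models, compute standard errors for kappa and the omegas,
#' and test the models against each other with a one-degree-of-freedom
#' likelihood-ratio test. Results are returned and, when `out_dir` is given,
#' written as both TSV and JSON with a provenance header.
#'
#' @param alignment A [codon_alignment()] or FASTA path.
#' @param tree A [clade_tree()], Newick string, or Newick file path with the
#'   foreground clade labelled `#1`.
#' @param out_dir Optional output directory (created if missing).
#' @param opts A [fit_opts()].
#' @param stop_policy Passed to [filter_codon_columns()].
#' @return List of class `run_report` with `m0`, `clades`, `lrt`, `table`
#'   (tidy summary data frame), and `files` (paths written, if any).
#' @export
run_fit <- function(alignment, tree, out_dir = NULL, opts = fit_opts(),
                    stop_policy = "error") {
  aln <- .as_alignment(alignment)
  tr <- .as_tree(tree)
  aln_f <- filter_codon_columns(aln, stop_policy = stop_policy)
  m0 <- fit_m0(aln_f, tr, opts)
  cl <- fit_clades(aln_f, tr, opts, init = m0)
  cl <- standard_errors(cl, aln_f, tr)
  m0 <- standard_errors(m0, aln_f, tr)
  lrt <- likelihood_ratio_test(m0, cl, df = 1L)
  tab <- data.frame(
    model = c("M0", "clades"),
    lnL = c(m0$lnL, cl$lnL),
    kappa = c(m0$kappa, cl$kappa),
    omega_0 = c(m0$omega[["omega_0"]], cl$omega[["omega_0"]]),
    omega_1 = c(NA, cl$omega[["omega_1"]]),
    se_omega_0 = c(m0$se[["omega_0"]], cl$se[["omega_0"]]),
    se_omega_1 = c(NA, cl$se[["omega_1"]]),
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(m0 = m0, clades = cl, lrt = lrt, table = tab,
         n_columns_used = aln_f$n_sites,
         n_patterns = .loglik_context(aln_f, tr)$n_patterns,
         files = character(0)),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(stage = "fit", seed = opts$seed,
                n_columns = aln_f$n_sites)
    tsv <- file.path(out_dir, "fit_report.tsv")
    .write_tsv(tab, tsv, .provenance(cfg))
    js <- file.path(out_dir, "fit_report.json")
    jsonlite::write_json(
      list(m0 = list(lnL = m0$lnL, kappa = m0$kappa,
                     omega = as.list(m0$omega), se = as.list(m0$se)),
           clades = list(lnL = cl$lnL, kappa = cl$kappa,
                         omega = as.list(cl$omega), se = as.list(cl$se)),
           lrt = list(delta = lrt$delta, df = lrt$df, p = lrt$p),
           n_columns_used = aln_f$n_sites,
           seed = opts$seed),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    report$files <- c(tsv, js)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== clade-model fit report ==\n")
  print(x$table)
  print(x$lrt)
  invisible(x)
}

#' Run the simulation stage
#'
#' Simulates a codon alignment under the partitioned model (see
#' [simulate_alignment()]) and writes the alignment (FASTA), the labelled
#' tree (Newick), and the ground-truth event table (TSV with a provenance
#' header including the seed).
#'
#' @param tree A [clade_tree()] or Newick input.
#' @param params A [codon_model_params()].
#' @param n_codons,seed,cpg_bias As in [sim_config()].
#' @param out_dir Output directory.
#' @return The `sim_result`, with `$files` listing what was written.
#' @export
run_simulate <- function(tree, params, n_codons, seed = 1L, cpg_bias = 1,
                         out_dir) {
  tr <- .as_tree(tree)
  cfg <- sim_config(tr, params, n_codons, seed = seed, cpg_bias = cpg_bias)
  sim <- simulate_alignment(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "simulated_alignment.fasta")
  write_alignment(sim$alignment, fa)
  nw <- file.path(out_dir, "simulated_tree.nwk")
  write_tree(tr, file = nw)
  prov <- .provenance(list(stage = "simulate", seed = seed,
                           n_codons = n_codons, cpg_bias = cpg_bias,
                           omega = paste(params$omega, collapse = ",")))
  tt <- file.path(out_dir, "truth_events.tsv")
  .write_tsv(sim$truth$events, tt, prov)
  ct <- file.path(out_dir, "truth_branch_counts.tsv")
  .write_tsv(sim$truth$branch_counts, ct, prov)
  sim$files <- c(fa, nw, tt, ct)
  sim
}

#' Run the ancestral-reconstruction stage
#'
#' Maximum-parsimony codon reconstruction with substitution classification
#' and CpG-deamination annotation, written as a TSV event table.
#'
#' @param alignment A [codon_alignment()] or FASTA path.
#' @param tree Tree input (used as rooted).
#' @param sites Tracked codon sites (default all).
#' @param out_dir Optional output directory.
#' @return The annotated `mp_reconstruction`, with `$files`.
#' @export
run_ancestors <- function(alignment, tree, sites = NULL, out_dir = NULL) {
  aln <- .as_alignment(alignment)
  tr <- .as_tree(tree)
  rec <- fitch_reconstruct(tr, aln, sites = sites)
  rec <- classify_substitutions(rec)
  rec <- annotate_cpg(
    rec,
    context_seqs = if (is.null(sites)) NULL else {
      # Context from a full reconstruction when only some sites are tracked.
      full <- fitch_reconstruct(tr, aln)
      apply(full$node_codons, 1L, paste, collapse = "")
    }
  )
  rec$files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "ancestral_events.tsv")
    .write_tsv(rec$events, path, .provenance(list(stage = "ancestors")))
    rec$files <- path
  }
  rec
}

#' Run the insertion-locus diagnostics stage
#'
#' TSD detection and endonuclease-site scanning on a genomic locus with a
#' known insert interval, written as TSV reports.
#'
#' @param locus Locus sequence (character) or FASTA path (first record).
#' @param insert_interval 0-based half-open insert interval.
#' @param out_dir Optional output directory.
#' @param max_mismatch,min_len Passed to [find_tsd()].
#' @return List of class `locus_report` with `tsd`, `en_sites`, `files`.
#' @export
run_locus <- function(locus, insert_interval, out_dir = NULL,
                      max_mismatch = 0L, min_len = 6L) {
  if (nchar(locus) < 500L && file.exists(locus)) {
    aln <- Biostrings::readBStringSet(locus)
    locus <- as.character(aln[[1]])
  }
  tsd <- find_tsd(locus, insert_interval, max_mismatch = max_mismatch,
                  min_len = min_len)
  en <- scan_en_sites(locus)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- .provenance(list(stage = "locus"))
    tsd_df <- if (is.null(tsd)) {
      data.frame(tsd_seq = NA, start5 = NA, end5 = NA, start3 = NA,
                 end3 = NA, mismatches = NA, en_site = NA)
    } else {
      data.frame(tsd_seq = tsd$seq, start5 = tsd$interval5[1],
                 end5 = tsd$interval5[2], start3 = tsd$interval3[1],
                 end3 = tsd$interval3[2], mismatches = tsd$mismatches,
                 en_site = tsd$en_site)
    }
    f1 <- file.path(out_dir, "tsd_call.tsv")
    .write_tsv(tsd_df, f1, prov)
    f2 <- file.path(out_dir, "en_sites.tsv")
    .write_tsv(en, f2, prov)
    files <- c(f1, f2)
  }
  structure(list(tsd = tsd, en_sites = en, files = files),
            class = "locus_report")
}
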