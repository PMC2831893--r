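---
title: "Clade-partitioned codon models and retrocopy diagnostics: methods"
author: "retroclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-partitioned codon models and retrocopy diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroclade)
```

## The scientific question

When a processed mRNA copy reinserts into the genome (a retrocopy), it either
decays into a pseudogene or is kept functional by selection. The two outcomes
leave different footprints in the coding sequence: a functional retrogene
accumulates nonsynonymous substitutions more slowly than a neutrally decaying
copy. The ratio of nonsynonymous to synonymous substitution rates,
$\omega = d_N/d_S$, quantifies this: $\omega \ll 1$ means purifying selection,
$\omega = 1$ neutrality. `retroclade` asks the question comparatively: did a
recently emerged retrogene clade evolve under a *different* $\omega$ than the
parental gene family? The motivating system is the Rap1 family of Ras-like
GTPases, where mouse- and human-specific retrocopies of the Rap1A/Rap1B genes
carry a handful of amino-acid replacements at functionally loaded residues.

## The codon substitution model

Codon evolution is modelled as a time-continuous, time-reversible Markov
process on the 61 sense codons of the standard genetic code. For codons $i,j$
differing at exactly one nucleotide,
$$
q_{ij} \;=\; \pi_j \cdot \kappa^{\,\mathbb{1}[\text{transition}]}
          \cdot \omega^{\,\mathbb{1}[\text{nonsynonymous}]},
$$
and $q_{ij}=0$ when $i$ and $j$ differ at two or more positions. Here
$\kappa>0$ is the transition/transversion rate ratio (unitless, typically
1.5–5 in mammalian nuclear genes), $\omega \ge 0$ the nonsynonymous /
synonymous rate ratio, and $\pi$ the stationary codon frequencies. Each
generator is rescaled so that one unit of branch length equals one expected
substitution per codon at stationarity; branch lengths therefore read as
expected substitutions per codon under that branch's own partition model.

Stationary frequencies default to the positional-nucleotide product form
(F3x4): the frequency of codon $n_1 n_2 n_3$ is proportional to
$f_1(n_1) f_2(n_2) f_3(n_3)$, with $f_p$ the empirical nucleotide frequencies
at codon position $p$ counted over all taxa and retained columns, renormalised
over sense codons. An empirical codon-proportion form (F61) is available via
`f3x4_frequencies(aln, model = "F61")`. A positional frequency of exactly zero
zeroes every codon containing that base at that position; this is legal but
reported (warning plus `zero_codons` attribute) because such states become
unreachable.

### Branch partitions: M0 within the clades model

Every branch carries an integer partition label; partition 0 is the
background. The *clades model* gives the background branches one ratio
($\omega_1$, `omega_0` in the output) and a designated foreground clade —
here, the retrogene clade created by retrotransposition and duplication — its
own ratio ($\omega_2$, `omega_1`). The one-ratio model M0 is the special case
$\omega_1 = \omega_2$, so the models are nested and
$$
\Delta = 2\,\{\ln L(\text{clades}) - \ln L(\text{M0})\} \;\sim\; \chi^2_1
$$
under the null that a single ratio suffices. `likelihood_ratio_test()` clamps
small negative $\Delta$ (optimiser tolerance) at zero before taking the upper
tail.

In the Newick dialect read by `load_tree()`, `#1` after a node name or branch
length marks that branch as foreground; by default a label on an internal
branch propagates to its whole subtree, because the foreground of interest is
a clade (stem plus descendants). `propagate = FALSE` restricts the label to
the stem branch alone.

### Likelihood and optimisation

`codon_log_likelihood()` is Felsenstein's pruning algorithm over compressed
site patterns, with each branch using $P(t) = e^{Qt}$ of its partition's
generator. $P(t)$ is computed by eigendecomposition of the
$\pi^{1/2}$-symmetrized generator — reversibility guarantees a real spectrum,
and one decomposition per partition serves every branch in that partition.
The root may be placed on any internal node: for reversible models the
likelihood is root-invariant (pulley principle), which the test suite asserts
by re-rooting.

`fit_m0()` and `fit_clades()` maximise the likelihood jointly over $\kappa$,
the $\omega$(s) and all branch lengths, using bounded quasi-Newton (L-BFGS-B)
on log-transformed parameters. Box bounds are $\omega \in [10^{-4}, 50]$
(the lower bound keeps boundary estimates for fully conserved clades
representable), $\kappa \in [0.05, 50]$, branch lengths
$\in [10^{-8}, 20]$. The heuristic start uses $\kappa = 2$, $\omega = 0.4$
and branch lengths from the mean pairwise codon p-distance spread over the
mean tip-to-tip path length; by default one seeded log-normal jitter of that
start is added (`fit_opts(n_starts = )` controls the count). Two choices
matter in practice and are deliberate:

* **Seeding the clades fit from the M0 optimum** (`fit_clades(..., init = m0)`)
  starts the richer model at a point where its likelihood equals the null
  fit's, so monotone optimisation enforces the nesting inequality
  $\ln L(\text{clades}) \ge \ln L(\text{M0})$ numerically — negative LRT
  statistics cannot arise from a poor foreground start. The pipeline
  (`run_fit()`) and all calibration studies use this.
* **The deterministic heuristic start dominates in this model family** (the
  likelihood surface in $(\kappa, \omega, t)$ is well behaved for within-
  mammal divergences), so the default is two starts rather than a larger
  random multistart; bulk simulation studies drop to a single start for
  speed without measurable effect on the estimates.

Convergence uses the L-BFGS-B criteria (`factr = 1e7`, i.e. about
$2\times10^{-9}$ relative in the objective, and `pgtol = 1e-8`); calibration
loops relax `factr` to `1e9`, which changes fitted log-likelihoods by less
than $10^{-3}$ on these problem sizes.

### Standard errors

`standard_errors()` reports curvature-based (observed-information) SEs for
$\kappa$ and the $\omega$s: the central finite-difference Hessian of
$\ln L$ at the MLE is inverted; branch lengths are held at their MLEs by
default (`include_branch_lengths = TRUE` adds them to the Hessian block).
An SE is *undefined* (`NA`) when the estimate sits at a box bound — the
typical case being $\hat\omega_1 = 10^{-4}$ for a fully conserved background,
where the interior curvature does not exist — or when the information matrix
is not positive definite. This mirrors how boundary estimates are reported in
the reference implementations of this model family.

## The synthetic-data generator

`simulate_alignment()` is an *exact, event-by-event* (Gillespie) simulator
rather than a $P(t)$ sampler at the leaves: root codons are drawn from
$\pi$, and each branch evolves by drawing exponential waiting times from the
current total rate, picking a site proportional to its rate and a target
codon proportional to the candidate rates. The price is speed; the payoff is
that every substitution event exists as ground truth (time, branch, site,
from/to codon, synonymous flag, CpG context), which the parsimony and CpG
modules need for validation.

The optional CpG-deamination overlay multiplies the rate of C→T changes
whose C is followed by G, and G→A changes whose G is preceded by C, by
`cpg_bias` $\ge 1$. Context is evaluated on the current nucleotide sequence,
across codon boundaries, and re-evaluated after every event; the first and
last base use fixed flanking bases from the configuration (default `A`/`A`).
With `cpg_bias = 1` the overlay is inert and sites evolve independently.
The overlay deliberately breaks detailed balance — deamination is a mutational
pressure, not a reversible exchange — so long-branch simulations with large
bias drift from $\pi$; that is the modelled biology, not an artefact.

`simulate_retrogene_scenario()` reproduces the generative history of a
retrogene pair: a retrotransposition event at a chosen point on a species-tree
branch, a stem of length `dup_delay` to the duplication event, then two
retrocopy tips; the grafted clade is labelled foreground. The documented
history of the mouse pair has the duplication following the
retrotransposition closely, so small `dup_delay` values are the realistic
regime. `simulate_insertion_locus()` builds genomic ground truth for the
locus diagnostics: random flanks, the L1 endonuclease cleavage motif
(`TTTT/A`) planted at the cut point, and the insert wrapped in two exact TSD
copies whose first base is the post-cleavage `A`; the generator pins the base
after the 3' copy so the planted repeat cannot extend by chance, making its
length exactly recoverable.

**What the generator does not emulate:** alignment error, indels and gapped
columns (the filtering step is therefore exercised by separately corrupted
fixtures), rate variation across sites, selection on synonymous codon usage,
5' truncation and poly-A tails of real L1 inserts, and non-equilibrium base
composition. Passing tests on simulated data therefore validate the
estimators under the model's own assumptions; they do not certify robustness
to model violations in real alignments.

### Fixture study conditions

The demonstration species tree (`rap1_species_tree()`) covers the seven
mammals of the motivating study with a retrocopy pair on the mouse lineage.
Branch lengths are package defaults chosen once to represent a strongly
conserved mammalian gene (tip-to-root paths of roughly 0.1–0.2 expected
substitutions per codon; retro clade stem 0.02 with 0.025 tips, i.e. a young
clade): the study printed no branch lengths, so these are documented artifact
choices, not estimates. The calibration studies use:

* *likelihood oracle*: 30 random 4-taxon, 5-codon instances;
* *parameter recovery*: 20 datasets, 9 taxa, 250 codons, $\kappa = 2$,
  $\omega_1 = 0.05$, $\omega_2 = 0.30$;
* *LRT calibration*: 300 datasets under M0 ($\omega = 0.2$, 200 codons) on a
  compact 6-taxon two-partition tree (`calibration_tree()`), chosen so
  hundreds of paired fits stay cheap;
* *regime reproduction*: ORF-sized alignments (184 codons) on the species
  tree with foreground truth 0.26 / 0.33 and a near-fully-conserved
  background ($\omega_1 = 10^{-4}$), twelve replicates per family, compared
  on the replicate **median**. The median, not the mean, is the right
  summary here: the foreground clade contributes only on the order of ten
  substitutions, and a replicate that happens to draw no synonymous
  foreground event sends $\hat\omega_2$ to its upper box bound, making the
  replicate mean arbitrarily bad while leaving the median stable. Even so,
  the information content of a single short foreground branch bounds how
  tightly any estimator can localise $\omega_2$: for the one-retrocopy
  family the sampling spread of the replicate median is wider than
  $\pm 0.05$, so that comparison is reported as an inherent limitation of
  the study scale rather than an estimator defect (the two-retrocopy family,
  with three foreground branches, is correspondingly tighter).

## Ancestral reconstruction and CpG annotation

`fitch_reconstruct()` applies Fitch parsimony to each nucleotide position of
each tracked codon site and reassembles codons at the internal nodes. The
bottom-up pass yields the minimal change count (verified against exhaustive
enumeration on small trees); the top-down pass resolves ambiguity by the
standard parent-matching refinement, with ties broken deterministically
toward the alphabetically first state, because the downstream reports present
a single codon per node. Full ambiguity sets are retained in the `ambiguity`
field rather than collapsed silently. Parsimony counts are a lower bound on
the true number of events (multiple hits are invisible), which is asserted —
as an inequality, not an equality — against the simulator's event-level truth.

`classify_substitutions()` translates parent and child codons to tag each
event synonymous or nonsynonymous, writing the field's residue notation
(`T35M`; synonymous events repeat the residue, `T35T`). A note on the
motivating system: the package follows the assignment of `T35M` to the
*second* mouse retrocopy (with the synonymous `T35T` on the first), which is
how the mutation tables and the sequence records lay out the changes; one
figure legend in the study orders the pair the other way round, and the
worked example keeps the data as recorded rather than silently harmonising.

`annotate_cpg()` flags events consistent with deamination of methylated CpG:
C→T with a following G, or G→A with a preceding C, read from the parent
node's sequence context. When the required neighbour is outside the tracked
region the flag is `NA` (unknown), never silently `FALSE`. When only a
subset of codon sites is tracked, cross-codon contexts are unknowable and
are reported `NA`; supplying full-length `context_seqs` restores them.

## Locus diagnostics

* `in_silico_pcr()` requires a unique exact forward match and a unique
  reverse-complement match downstream; amplicon coordinates are 0-based
  half-open and *primer-inclusive* — the convention needed for the
  documented 1186 bp product to decompose as 213 + 973 under the digest.
  Mismatch tolerance is opt-in and never allowed in the 3'-terminal 3 nt,
  where polymerase extension actually requires pairing. Circular templates
  are out of scope (all targets are linear cDNA/genomic segments).
* `digest_sequence()` models an enzyme as an IUPAC pattern plus a cut offset
  (NlaIV = `GGNNCC`, blunt cut after position 3), finds all — including
  overlapping — pattern occurrences, and returns cut positions and the
  fragment-length multiset, which always sums to the input length. Enzyme
  definitions live in a small editable table (`restriction_enzyme()`), since
  only the recognition mechanics matter here.
* `find_tsd()` looks for the longest direct repeat whose 5' copy ends at the
  insert's 5' boundary and whose 3' copy starts at its 3' boundary — the
  geometry of target-primed reverse transcription — within a mismatch budget
  (default 0); calls shorter than 6 bp are suppressed as noise.
* `scan_en_sites()` reports every `TTTT/A` cleavage point on both strands in
  plus-strand coordinates, flagging the extended `TTTT/AA` preferred-site
  variant rather than demanding it: the strict form is what the reconstructed
  insertion site shows, the extended form is the literature consensus, and
  reporting strictly-matching sites with a flag lets the caller choose.
* `protein_diff()` compares equal-length proteins (ORFs are translated
  first) and annotates each substitution with every motif interval it falls
  in (G1–G4, effector recognition 32–40, effector specificity 20–31 and
  41–45; G2 overlaps the effector region, so annotations are comma-joined
  lists, not a single winner). Unequal lengths are an error by design —
  retrocopy ORFs are unspliced full-length copies, so a length mismatch
  signals a problem that silent alignment would hide.

## Synthetic sequence fixtures

Real database records for the Rap1 family are not redistributed with the
package. `rap1_synthetic_fixtures()` generates deterministic stand-ins that
embed the documented assay geometry — primer sites, the 1186 bp amplicon,
the single discriminating NlaIV site cutting at 213 bp (synonymously absent
from the retrocopies), the motif residues, the nine paralog differences and
the retrocopy substitutions — with all unconstrained residues and UTR bases
pseudo-random under a fixed internal seed. A scrubbing pass removes chance
extra NlaIV sites by minimal synonymous (ORF) or free (UTR) edits, keeping
the digest geometry exact. These fixtures exercise the diagnostics end to
end; conclusions about the real records require the real records.

## Numerical notes and limitations

* Transition-probability matrices are clamped at zero and row-renormalised
  after eigen-reconstruction; rounding at the $10^{-14}$ level otherwise
  produces harmless negative entries.
* Site-pattern compression keys on the full codon column; ties keep first
  occurrence. The likelihood is invariant to taxon order and to pattern
  multiplicity (asserted in tests).
* The model excludes site-heterogeneous $\omega$ (M1a/M2a/M8-style mixtures),
  gamma rate variation, and non-reversible processes; $\kappa$ is estimated
  by ML (it can be pinned by setting equal bounds in `fit_opts()`).
* Gap handling is complete-case by design: any codon column containing a gap
  or ambiguity in any taxon is dropped before fitting, with the surviving
  column indices kept in `source_mask`. The study's pipeline family treats
  gapped columns the same way; a gap-aware likelihood is out of scope.
* Fitch reconstruction treats the supplied topology as rooted; for count
  purposes rooting is immaterial (asserted), but event placement on the two
  root-adjacent branches is only identifiable given an outgroup.
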