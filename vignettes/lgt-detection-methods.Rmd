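---
title: "Detecting and characterizing bacterial-to-insect lateral gene transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing bacterial-to-insect lateral gene transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgthunter)
```

# The problem

Bacteria-to-eukaryote lateral gene transfers (LGTs) are an under-appreciated
source of new animal genes, but calling one from assembly data alone is
risky: bacterial contamination of sequencing libraries produces chimeric or
purely bacterial scaffolds, and deeply conserved housekeeping genes align
well to bacteria for reasons that have nothing to do with transfer.  A
credible LGT call therefore rests on a chain of evidence: a genomic region
that looks much more bacterial than animal, located on a well-assembled
scaffold next to ordinary host genes; conservation of that arrangement
across independently assembled relatives (microsynteny); purifying
selection on the coding sequence (dN/dS well below 1); phylogenetic nesting
of the protein inside the bacterial clade; and, where bench work is
possible, PCR across the LGT/host-gene boundary and degenerate-PCR surveys
across related taxa.  `lgthunter` implements that whole chain as testable
code, with a simulator that generates ground-truthed inputs for every link.

# The differential-homology screen

The screen searches every scaffold of the focal assembly against a
bacterial nucleotide database with the package's own seed-and-extend local
aligner.  Regions with a bacterial E-value below `1e-5` are candidate LGTs.
Two filters then remove the classic false positives:

* **Animal filter.** The candidate region (not the whole scaffold) is
  searched against a panel of animal genomes.  If the best animal E-value
  is *strictly* smaller than the bacterial one, the region is better
  explained as a slowly evolving conserved gene and is excluded.  Ties
  retain, because the rule is a strict inequality.
* **Scaffold-length filter.** Candidates on scaffolds shorter than 5 kb are
  excluded: short scaffolds are disproportionately assembled from
  environmental (contaminant) DNA, so nothing on them can be distinguished
  from contamination by homology alone.

Nucleotide rather than protein search is deliberate: DNA homology decays
quickly, so an intact high-identity DNA match to bacteria points to a
recent-enough transfer rather than an anciently conserved protein motif.

Every candidate is reported, excluded or not, with an ordered audit trail
naming each filter and its decision.  The screen's calls depend only on
E-value *comparisons*, which motivates several numerical choices below.

Regions are built by merging significant HSPs on a scaffold that lie within
`hsp_merge_gap = 1000` bp of one another — a gene-scale gap; the merge
width is recorded in output metadata.

# The alignment engine and its statistics

The local aligner is BLAST-like: exact 11-mer seeding for DNA on both
strands (word hits on the reverse complement carry strand `-`),
neighborhood 3-mer seeding with a score-11 threshold for proteins, ungapped
X-drop extension, then gapped refinement by a banded local
dynamic-programming pass around the seed diagonal.  Scoring defaults are
match +2 / mismatch -3, gap open 5 / extend 2 for DNA, and BLOSUM62 with
gap open 11 / extend 1 for proteins; `N` and `X` score as the worst
mismatch and never seed.  A gap of length *k* costs `open + k * extend`.

Significance uses Karlin–Altschul theory: `lambda` is the positive root of
the background expectation equation (solved to a residual below `1e-10`)
and `K` comes from the standard lattice computation over convolutions of
the single-pair score distribution.  On the default DNA scheme this yields
`lambda = 0.634`, `K = 0.408`.  Three simplifications are documented
package decisions: gapped alignments reuse the ungapped `lambda`/`K`; no
composition-based statistics; no effective-length correction (`E = K m n
exp(-lambda S)` with raw lengths).  All three shift E-values by
comparable factors on the comparisons the screen actually makes, so
decisions are preserved even though absolute E-values are approximate and
deliberately conservative.

E-values are additionally carried in log10 form and every comparison in the
screen is made on that scale.  kb-scale near-exact hits have E-values far
below the smallest positive double, and comparing linear zeros would turn
the strict animal-vs-bacterial inequality into spurious ties.

# Orthology, identity background and microsynteny

1:1 orthologs are reciprocal best protein hits, with deterministic
tie-breaking (minimum E, then higher score, then lexicographically smaller
subject id).  The focal pair's amino-acid identity — measured over the
aligned columns of the best HSP, since no single convention is universal —
is placed against the distribution of identities of all other 1:1
orthologs as a Z-score using the sample standard deviation (`n - 1`); the
background size is reported alongside so the comparison is auditable.  An
unremarkable Z-score is evidence that the candidate has resided in these
genomes as long as ordinary orthologs have.

Microsynteny takes the `window = 4` genes on each side of the focal gene in
each assembly and reports the fraction of flanking genes whose 1:1 ortholog
lands inside the partner window (denominator clipped at scaffold ends), and
whether the shared orthologs appear in the same relative order, counting a
whole-window reversal as conserved since scaffold orientation is
arbitrary.  The nearest-neighbor gap (end-to-start, 0 when overlapping,
ties broken downstream) defines the bridging interval a wet-lab PCR would
amplify across the LGT/host-gene boundary.

# dN/dS

Codon alignments are built by globally aligning the translated proteins
(Needleman–Wunsch, BLOSUM62) and back-translating; residue gaps become
codon gaps, and gap columns are dropped pairwise before estimation, the
pairwise codeml convention.

Two estimators are provided.  **NG86** counts per-codon
synonymous/nonsynonymous site fractions (averaged over the two sequences;
mutations to stop codons are excluded and the fractions rescaled to sum
to 3) and difference counts averaged over all minimal substitution
pathways, discarding pathways through stops; Jukes–Cantor correction
`d = -3/4 log(1 - 4p/3)` maps proportions to distances and is undefined at
`p >= 3/4`, which the function reports as an error rather than
extrapolating.  **ML** fits a Goldman–Yang-style 61-state codon model:
single-nucleotide changes have rate proportional to the target codon's
equilibrium frequency, times `kappa` for transitions and `omega` for
nonsynonymous changes; multi-nucleotide changes have rate 0.  Equilibrium
frequencies are F3x4 (products of codon-position nucleotide frequencies of
the pair, floored at `1e-6` to avoid structural zeros), the generator is
scaled to one expected substitution per codon per unit time, and the
likelihood is the reversible pairwise form `pi_i P_ij(t)` summed over
columns, with `P(t)` by eigendecomposition of the pi-symmetrized
generator.  `(t, kappa, omega)` are maximized by Nelder–Mead on log
parameters from three fixed starts, to a relative tolerance of `1e-10`;
alignments with no variable columns return the `t = 0` boundary with a
warning.  `dN` and `dS` derive from the fitted divergence and the model's
synonymous/nonsynonymous flux, with site totals computed at `omega = 1`;
under this convention `dN/dS` equals the fitted `omega` exactly.  A floor
of 10 non-gap codons guards against meaningless fits.

The package's own simulator (`simulate_codon_pair`) draws an ancestor from
the F3x4 stationary distribution and evolves two lineages for `t/2` each by
exact transition-probability sampling.  Parameter recovery on this
simulator (20 replicates of 2000 codons at `omega` 0.062, 0.5 and 1.0,
within 15% relative bias) is part of the acceptance suite.  Because the
simulator and estimator share the generator construction, the counting
estimator (NG86) and an exhaustive pathway-enumeration oracle written
independently in the tests provide the cross-checks that guard against a
self-confirming model.

# Phylogenetic placement

Full Bayesian tree inference is out of scope; the decision-relevant output
— does the focal protein nest inside the bacterial clade with strong
support? — is preserved by a lightweight distance pipeline:
Poisson-corrected distances (`d = -log(1 - p)`) with pairwise deletion (to
tolerate ragged domain trims), Saitou–Nei neighbor joining with
lexicographic tie-breaking and negative-branch clamping (deficit moved to
the sister branch, preserving their sum), and nonparametric bootstrap over
alignment columns.  The origin call examines, among internal edges with
support at or above 0.8 (mirroring the ">80% bootstrap" convention for a
trustworthy node), the one whose focal-containing side is smallest: all
bacterial neighbors gives `bacterial_nested`, all eukaryotic
`eukaryotic_nested`, anything else (or no supported edge) `ambiguous`.

# Degenerate primers and in-silico PCR

Conserved gap-free blocks of a DNA alignment are reduced per column to the
minimal IUPAC code covering the observed bases (no frequency weighting —
the design case is a two-sequence alignment), and windows whose cardinality
product stays within a degeneracy budget become primers; reverse primers
are IUPAC-aware reverse complements.  Primer length is clipped to 18–27 nt
by default — conventional primer lengths that also admit both published
survey primers used as worked examples (23 and 20 nt, degeneracies 128 and
96).  In-silico PCR matches degeneracy-aware (a template base matches a
code iff it belongs to the code's set), allows one mismatch outside an
exactly matching 3-base 3' anchor (polymerase extension is most sensitive
to 3'-terminal mismatches), requires non-overlapping sites in proper
orientation, and caps products at 5 kb — PCR-realistic defaults; products
are reported with coordinates and per-primer mismatch counts.

# The simulator: what it emulates, and what it does not

`simulate_screen_inputs` builds, from one seed, the full screen exercise:
a three-scaffold 50 kb host assembly at GC 0.35 with ten intronless
900 bp genes per scaffold; a 2 kb bacterial donor gene (GC 0.40) implanted
intergenically at 10% divergence — the scale at which a transfer tens of
millions of years old still shows DNA homology; a conserved-gene decoy
copied into the bacterial database at 25% divergence and into the animal
database at 5%, so its animal E-value must win; and a 3 kb pure-bacterial
contaminant scaffold below the 5 kb floor.  Divergence values that the
source analysis does not pin down were chosen once as field-realistic and
are recipe parameters, not test knobs.  Implants replace intergenic host
sequence rather than inserting, so annotated gene coordinates remain valid
and ground-truth intervals stay exact.

Mutations are uniform substitutions without indels: E-value-based screening
decisions do not require realistic indel structure, and indel-free ground
truth keeps implanted intervals exact.  Likewise there is no repeat
content, no sequencing-error model and no codon-usage realism beyond F3x4.
Passing tests on these fixtures therefore demonstrate the *logic* of the
pipeline — filters, statistics, estimators, classifications — not
robustness to assembly artifacts of real genomes.

Every generator saves and restores the caller's RNG state and is a pure
function of its seed; seeds are recorded in output metadata.

# Numerical and design notes

* Internal coordinates are 0-based half-open; all human-readable outputs
  are 1-based inclusive, stated in each writer.
* The engine's gapped refinement is banded around the seed diagonal
  (half-width 50), so its score is a valid local alignment score bounded
  above by full Smith–Waterman; the bound, and equality on ungapped-similar
  pairs, are asserted against an independent implementation in the tests.
* HSPs contained within a higher-scoring HSP (same subject and strand) are
  dropped; overlapping same-diagonal seeds extend once.
* `identity_zscore` refuses a zero-variance background rather than
  returning an infinite score.
* NJ ties (exactly equal Q values) are resolved by the lexicographically
  smallest pair of cluster labels, making star-like inputs deterministic.
* The end-to-end two-species fixture evolves the implanted gene pair under
  the codon model at `omega = 0.062` — the published estimate for the
  monarch/silkworm GH31 pair — so the pipeline's selection stage sees
  realistic purifying selection.
* Problem sizes in the test and acceptance suites (2000-codon alignments,
  20 replicates, 50 kb assemblies, 100 bootstrap replicates) were chosen
  as the smallest scales at which the statistical guarantees are stable.

# Known limitations

* Absolute E-values are approximate (ungapped statistics, no length
  correction); only E-value comparisons are contract-level behavior.
* The reported amino-acid identity of an ortholog pair is BLAST-local
  (best-HSP columns); global-alignment identity can differ by a few points
  on gappy pairs.
* NG86 without a transition/transversion correction underestimates
  synonymous saturation at high divergence; the ML estimator is the
  primary tool and NG86 the cross-check.
* The placement stage expects a pre-trimmed, pre-aligned protein panel;
  domain detection and multiple alignment are upstream concerns.
* Reproducing the published GH31 numbers requires the real MonarchBase,
  SilkDB and DBM gene sets, which are external downloads
  (`reproduce_published_comparison` documents the expected layout).
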