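---
title: "Methods: motif discovery and characterization in mitochondrial D-loops"
author: "dloopmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif discovery and characterization in mitochondrial D-loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most mitochondrial DNA replication events terminate prematurely a few
hundred nucleotides after initiation, leaving the nascent strand bound to
its template as a triple-stranded displacement loop (D-loop) in the
control region. The boundaries of this region harbor short sequence
elements that are conserved across vertebrates: at the 3′ end, within the
extended termination-associated sequence (ETAS1), sits a ~15 nt element
built from two strongly conserved triplets, ATG and CAT, separated by a
more variable 9 nt spacer (often called coreTAS); a closely related
element lies on the opposite strand inside conserved sequence block 1
(CSB1) at the 5′ end, and a rarer variant carries a 10 nt spacer. Both
elements are approximately palindromic — each resembles its own reverse
complement — and in some taxa they occur as tandem copies separated by
2–3 nt.

`dloopmotif` implements the comparative-genomics pipeline that finds and
characterizes such elements: D-loop extraction from annotated
mitochondrial genomes, redundancy reduction, de novo ungapped motif
discovery by expectation-maximization, iterative profile-based homology
search, and structural characterization (anchors, spacer, palindromy,
strand merging, tandem arrangement, variant-density overlay). A
synthetic-data module generates D-loop-like sequence sets with planted
ground truth, so every stage is testable end to end without any
network access.

## Pipeline stages and their models

### Extraction (`read_genomes`, `extract_dloop`)

D-loops are taken from GenBank annotation: the first feature whose key
matches `D-loop` or a `misc_feature` whose qualifier text contains
"control region" (the accepted key set is configurable, because
annotation practice varies across taxa). Mitochondrial genomes are
circular and the control region typically spans the numbering origin;
a location such as `join(16024..16569,1..576)` is linearized in the
stated join order and flagged `wraps_origin`. All internal coordinates
are 0-based half-open; the single conversion from GenBank's 1-based
inclusive convention happens at parse time, nowhere else. Extraction
always takes the forward (L-strand) orientation; strand is an inference
of motif discovery, not of extraction. IUPAC ambiguity codes other than
N are mapped to N with a logged count, because the motif model is
4-letter with N handled explicitly.

### Redundancy filtering (`pairwise_identity`, `filter_redundancy`)

Public sequence collections over-represent some taxa; motif discovery
on such a set would simply learn the best-sampled clade. The filter
retains a subset in which every pair is below 90% identity. Identity is
computed from a global (Needleman–Wunsch) alignment with match +1,
mismatch −1, and affine gap costs (open 5, extend 1; a run of L gaps
costs `5 + L`), with the alignment length — including gap columns — as
the denominator. This is the strictest of the common dialects; a
"shorter sequence length" denominator is available as an option. N
matches nothing, including another N.

Selection is greedy in input order (as in CD-HIT): a record is kept iff
its identity to every already-kept record is below the threshold, and
each dropped record names the first kept record that excluded it.
Greedy first-come selection is deterministic and directly verifiable by
exhaustive re-alignment of the kept set, which both the test suite and
the acceptance script perform. An optional k-mer prefilter (k = 8)
skips the alignment when the shared 8-mer fraction is below 0.2 —
unrelated 900 nt sequences share only ~1.5% of 8-mers, while any pair
near the 90% threshold shares most of them — and tests verify that the
prefiltered and unprefiltered runs select identical sets.

### ZOOPS motif discovery (`zoops_em`, `erase_and_repeat`)

The discovery model is the classical ZOOPS (zero-or-one occurrence per
sequence) mixture. A motif of width $w$ is a position probability
matrix $\theta$ with a 0-order background $b$ and a site prior
$\gamma$. For sequence $i$ with $m_i$ admissible (offset, strand)
slots, the E-step posterior of a site at slot $j$ is

$$Z_{ij} \propto \frac{\gamma}{m_i}\prod_{k=1}^{w}
\frac{\theta_{k,x_{i,j+k}}}{b_{x_{i,j+k}}},\qquad
Z_{i0} \propto 1-\gamma,$$

normalized together per sequence. The M-step re-estimates $\theta$
from posterior-weighted site counts plus pseudocounts $\beta b$
($\beta = 0.25$ total per column) and $\gamma$ as the mean
per-sequence site probability. N (and erased) positions contribute
odds ratio 1. Iteration stops when the log-likelihood changes by less
than `tol` (default 1e-6) or after `max_iter` (200). In both-strand
mode the slot set doubles with reverse-complement windows, which is
what lets one motif absorb instances of an element that lives on
either strand.

Two numerical choices deserve emphasis:

* **Monotonicity is asserted on the penalized objective.** With
  pseudocounts, the quantity EM provably never decreases is the data
  log-likelihood plus the Dirichlet-style log prior implied by the
  pseudocounts. The package checks that penalized objective on every
  iteration of every run (tolerance 1e-8) and aborts on violation;
  the reported `trace` is the data log-likelihood.
* **Starts are data substrings chosen by a prescreen.** Planted or real
  sites occupy ~1.5% of a 900 nt sequence, so a handful of uniformly
  sampled substring seeds would rarely touch one and EM would settle in
  a background local optimum. The package deterministically samples a
  pool of `max(5 * n_starts, 100)` distinct substrings, scores each
  seed with a single E-step, and runs full EM from the `n_starts` best
  — the standard remedy for EM's start sensitivity in motif discovery.
  All randomness flows from the one `seed` argument.
* **Converged runs are phase-polished.** EM cannot escape a
  column-shifted local optimum (the element sitting one or two columns
  off-center in its window, possibly clipped at an edge) by ordinary
  iterations, because shifting is a large coordinated move. At
  convergence each run therefore evaluates column-shifted copies of the
  PPM (±3, vacated columns refilled with background and given one E/M
  refinement so they can be re-learned) and resumes EM from a shift
  that improves the likelihood, up to three times. Without this polish
  a 16 nt core inside an 18 nt window reliably settles one phase short
  of containing both anchors.

Occurrences are reported where the best per-sequence posterior reaches
0.5; multiple motifs are found by erasing (masking to N) positions
covered by occurrences with posterior ≥ 0.5 and repeating, stopping
early when the best remaining motif carries less than 1 bit of total
information. Motif significance is reported as total information
content and log-likelihood gain over the background-only model; no
E-value is computed.

On background-only data the package's null behaviour is worth knowing:
EM is free to align the most mutually similar windows it can find, so
the best "motif" on pure noise still concentrates roughly
$\log_2(\text{windows per sequence})$ bits into its columns, and
individual columns of a null motif routinely exceed 1 bit at the
problem sizes used here. Null discovery is therefore diagnosed by the
site prior $\gamma$ — which shrinks with the number of sequences on
null data and stays near the planted prevalence on signal — and by the
gap in total information content relative to a recovered element, not
by any fixed per-column threshold.

### Iterative profile search (`build_profile`, `score_sequence`, `iterate_search`)

Homology search for an element family proceeds by iterated profile
refinement. An alignment of the current members is condensed into a
linear match/insert/delete profile: columns with ≥ 50% residue
occupancy become match states; match emissions are smoothed column
counts (pseudocount `0.25 · background`); insert emissions are the
background; transitions come from the per-sequence state paths with
Laplace add-one smoothing (so with four aligned sequences the dominant
match–match transition is 5/7 ≈ 0.71, approaching 1 as the alignment
deepens). Sequences are scored by best-path (Viterbi) log2-odds under a
glocal regime — global in the profile, local in the sequence, with free
flanks — because the element is short relative to a D-loop and the
inclusion rule is a hard bit threshold; the best-path formulation also
yields the hit interval directly. Each round re-admits every database
sequence scoring at least `include_bits` (default 10 bits, exposed in
the interface since no principled universal cutoff exists), filters the
members for redundancy, realigns them with an in-package center-star
progressive aligner (externally produced aligned FASTA can be supplied
instead — both sources feed `build_profile` identically), rebuilds the
profile, and repeats until the member set repeats (a fixed point, which
the tests re-verify by running one extra round) or `max_rounds` is
reached.

### Characterization (`trim_core`, `palindromy`, `strand_merge`, `find_tandem`, `variant_overlay`)

Discovery windows (width 18 by default) are deliberately wider than the
element, so the conserved core must be trimmed out: the core spans the
first through last column with information content ≥ 0.5 bits, and
anchors are the maximal runs of ≥ 3 consecutive columns with ≥ 1 bit
nearest the core edges, reported as consensus triplets. The spacer is
the columns strictly between the anchor triplets. These thresholds
operationalize "strongly conserved triplets around a variable spacer"
and are configurable.

Palindromy and motif merging share one similarity: the mean per-column
similarity $1 - \tfrac12\lVert p - q\rVert_1$ (bounded in [0, 1] and
well-defined for near-deterministic columns, unlike a correlation),
maximized over column offsets within ±3 and — for merging — over
direct and reverse-complement orientation. Offsets beyond ±3 are
unnecessary because related motifs share a 15 nt core inside an 18 nt
window. A motif is called palindromic at score ≥ 0.7; motifs cluster by
single linkage at similarity ≥ 0.8. A motif always merges with its own
reverse complement, which is exactly how the two opposite-strand
elements collapse into one motif when both strands are analysed.

Tandem arrangement is measured on scan occurrences (the ZOOPS reporter
is capped at one site per sequence by construction, so tandem analysis
uses the PWM scanner `scan_motif`): per sequence and strand, the gap
`next.start − prev.end` between consecutive copies, with overlapping
pairs excluded and counted separately, and the modal gap reported
(smallest mode on ties).

Variant overlay assigns per-position variant counts (e.g. human
population variants) to the motif column each position overlaps,
strand-aware — column 1 is the motif's 5′ end on its own strand — with
positions inside several occurrences assigned to the first so that
count mass is conserved. Column densities (counts per occurrence)
classified into anchor/spacer columns quantify the depletion of
variation at the anchors. Motif columns are exported for logos in two
dialects, entropy-scaled heights and background-relative log-odds
heights, because logo conventions differ between the two.

## The synthetic generator: what it emulates and what it does not

`simulate_dloops` draws iid sequences over a skewed background
(defaults A 0.31, C 0.25, G 0.13, T 0.31 — the G-poverty of the
mammalian control region's L-strand; a modelling choice, exposed in the
configuration). With probability γ (default 0.8) a sequence receives
one planted element at a uniform admissible offset: anchor ATG, spacer,
anchor CAT, with anchor bases substituted independently at rate ε
(default 0.05) and the site reverse-complemented for minus-strand
placements. Options plant tandem copies with configurable gaps, append
near-duplicate star clusters (children mutated from a parent at the
rate that targets a configured identity) for the redundancy filter, and
emit per-position variant counts on the first sequence's coordinates
with the anchor-position rate divided by a depletion factor. Everything
derives from one integer seed; the same seed reproduces FASTA and
manifest byte for byte.

The default spacer is variable but not featureless: spacer bases are
drawn from a fixed weak consensus (an ATG/CAT-free pattern) with
substitution rate 0.25, putting ~0.6 bits in each spacer column —
clearly above background and clearly below the 1-bit anchor criterion,
which is the shape real logos of the element display. This choice is
also what makes site-level recovery well-posed at realistic scale: an
element reduced to its six anchor bases carries ~11 bits, barely above
the ~9.8-bit multiple-testing burden of 883 windows per 900 nt
sequence, so with a fully random spacer chance ATG–9nt–CAT windows
appear in roughly a quarter of the sequences and are statistically
indistinguishable from planted sites. A fully iid spacer remains
available (`spacer_consensus = NULL`) for exactly that kind of
hardness experiment.

What the generator does **not** emulate: vertebrate phylogeny (sequences
are iid; redundancy is star-shaped, not tree-shaped), indel evolution
within elements, length variation of the control region, and regional
composition heterogeneity. Passing tests on synthetic data therefore
demonstrate that the algorithms recover what was planted under the
stated noise model — not that any particular biological collection will
yield the same motifs.

## Validation scale and determinism

The validation suite exercises discovery at 200–300 sequences of
900 nt (the structural-recovery and redundancy checks), with smaller
problem sizes for the exhaustive-enumeration oracles (alignments of
2–5 nt for the brute-force aligner, ≤ 4-state profiles against ≤ 6 nt
targets for the Viterbi path enumeration, 3 toy sequences for the
E-step enumeration). These sizes were chosen so that each oracle is a
genuinely exhaustive computation. The acceptance script
(`scripts/acceptance.R`) regenerates data, reruns discovery, and
reports the recovered structural numbers; all of its randomness derives
from the `--seed` argument.

Reverse-complement symmetry of both-strand discovery is exact in the
model but only floating-point-exact in computation: mirrored data
change summation order, so final log-likelihoods of mirrored runs agree
to ~1e-4 rather than machine precision, and the tests assert the
motif-level statement (identical up to reverse complement) together
with that numerical band.

## Known limitations

* **Composition artifacts bound the useful sequence length of
  both-strand discovery.** The ZOOPS likelihood of a
  composition-extreme motif (e.g. G/A-rich against this G-poor
  background) grows with the number of windows scanned per sequence,
  because the model may pick each sequence's single most extreme
  window. On 600–900 nt sequences scanned on both strands that
  selection gain overtakes a ~16-bit element even when the background
  model is exactly correct, and the maximum-likelihood motif is junk —
  a property shared by any 0-order-background ZOOPS implementation,
  and the reason such tools report many motifs for a human to sift
  rather than only the top one. Both-strand validation in this package
  therefore runs on ~200 nt element-bearing regions, where the element
  is the global optimum; on real data the practical remedies are the
  same as ever: analyse subregions, request several motifs and erase,
  or supply a richer background.
* Motifs are ungapped and of fixed width; OOPS/multiple-occurrence
  models and gapped motifs are out of scope.
* No E-value calibration is attempted for either the EM motifs or the
  profile bitscores; thresholds are explicit knobs.
* The greedy redundancy filter guarantees the pairwise threshold but
  not a maximum-cardinality subset; permuting the input can change
  which representative survives (never whether the threshold holds).
* The center-star aligner is adequate for the short, highly similar
  regions the iteration realigns; it is not a general multiple aligner,
  and an external alignment can be substituted wherever one is
  accepted.
* `variant_overlay` works on a single coordinate system (one reference
  sequence) per call.
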