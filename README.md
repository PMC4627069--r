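# dloopmotif

Comparative-genomics toolkit for conserved sequence elements of the
vertebrate mitochondrial control region (D-loop).

The mitochondrial D-loop — the triple-stranded structure left behind when
most mtDNA replication events terminate prematurely — is bounded by short
sequence elements conserved across vertebrates. The best characterized is
a 15 nt element built from two strongly conserved triplets, `ATG` and
`CAT`, separated by a more variable 9 nt spacer; a reverse-complement
relative sits at the opposite end of the D-loop (within conserved sequence
block 1), a rarer variant carries a 10 nt spacer, and in some taxa the
element occurs in tandem copies 2–3 nt apart. Both elements are
approximately palindromic. `dloopmotif` implements the computational
pipeline that discovers and characterizes such elements:

* **mito_io** — parse annotated mitochondrial genomes (GenBank flat
  files), extract D-loop/control-region features — including features that
  wrap the numbering origin of a circular genome — and round-trip FASTA.
* **redundancy** — global-alignment percent identity (Needleman–Wunsch,
  affine gaps) and a greedy filter retaining a subset in which every pair
  is below 90% identity.
* **motif_em** — ungapped motif discovery by expectation-maximization
  under the ZOOPS model (zero or one site per sequence): for sequence $i$
  with $m_i$ admissible (offset, strand) slots, the E-step posterior of a
  site at slot $j$ is
  $Z_{ij} \propto \frac{\gamma}{m_i}\prod_k \theta_{k,x_{j+k}}/b_{x_{j+k}}$
  against a no-site mass $1-\gamma$; the M-step re-estimates the position
  probability matrix $\theta$ (with $0.25\,b$ pseudocounts) and the site
  prior $\gamma$. Single- and both-strand modes, multiple motifs by
  erasure, minimal motif-exchange text and BED6 output.
* **profile_iter** — iterative profile search: build a match/insert/delete
  profile from an alignment, score sequences by glocal (global-in-profile,
  local-in-sequence) Viterbi log2-odds, admit hits above a bit threshold,
  realign, re-filter, rebuild, iterate to a fixed point.
* **characterize** — core trimming by information content, anchor-triplet
  and spacer extraction, palindromy scoring, strand merging of related
  motifs, tandem-copy distances, and per-column variant-density overlay.
* **synthetic** — a generator of D-loop-like sequence sets with planted
  ground truth (sites, strands, tandem copies, near-duplicate clusters,
  anchor-depleted variants) for end-to-end validation.

## Worked example

Plant the conserved element in 300 synthetic 900 nt D-loop-like sequences
(site prevalence 0.8, anchor substitution rate 0.05), rediscover it, and
read off its structure:

```r
library(dloopmotif)

sim <- simulate_dloops(sim_config(n_seqs = 300, seq_len = 900,
                                  gamma = 0.8, seed = 101))
m <- zoops_em(sim$records, width = 18, strand_mode = "one_strand",
              seed = 1, n_starts = 20)
m
#> motif_model  width 18  mode one_strand
#>   consensus  ATATGTACTAATTACATA
#>   gamma 0.774  sites 223  total IC 15.7 bits  loglik -360205.8

trim_core(m)
#> anchor_report: core 3 - 17 (width 15)  anchors ATG / CAT  spacer 9 nt

score_recovery(m$occurrences, sim$manifest, slack = 3)[c("recall", "precision")]
#> $recall
#> [1] 0.8765432
#>
#> $precision
#> [1] 0.955157
```

The discovery window (18 nt) is wider than the element, so `trim_core`
trims it to the informative 15 nt core and reports the two anchor
triplets (`ATG`, `CAT`) with the 9 nt spacer between them — the structure
of the element as it appears in real vertebrate D-loops. `gamma` is the
fitted fraction of sequences carrying a site (0.77, versus 0.8 planted),
and recall/precision score the reported site locations against the
generator's truth manifest.

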