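---
title: "Methods: long-read RenSeq curation, capture assessment and novel NLR triage"
author: "renseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read RenSeq curation and novel NLR triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renseqr)
```

## The problem

Plant disease-resistance genes usually encode NLR immune receptors
(nucleotide-binding leucine-rich repeat proteins). NLR genes occur in
clusters of near-identical paralogs, which makes them hard to resolve with
short reads. Resistance gene enrichment sequencing (RenSeq) captures NLR
loci with tiled biotinylated baits and sequences the enriched library on a
long-read platform. Long reads span whole genes and their flanks, but the
platforms' indel-rich error profiles create their own problems: amplification
adapters and PCR-fusion chimeras must be removed before assembly, motif-based
NLR annotation is frameshift-sensitive, and distinguishing a *novel* NLR from
a noisy read of a known one requires an explicit statistical rule.

`renseqr` implements the computational stages of such a workflow as ordinary
R functions: read curation, on-target scoring, read/assembly quality
statistics, motif-based NLR classification, best-hit assembly evaluation, and
an empirical-threshold triage for novel-gene discovery, together with a
deterministic simulator so that every stage can be exercised and verified at
desk scale with known ground truth.

## The alignment engine

All stages share one pairwise engine (`local_align()`, `map_reads()`,
`semiglobal_locate()`), written for this package rather than wrapped from an
external aligner so its conventions are fixed and testable:

* **Scoring.** Affine-gap local alignment (Gotoh) with match +2,
  mismatch −3, gap open −5 and gap extension −2; a gap of length $L$ scores
  $-5 - 2L$. These are common nucleotide-search defaults and are
  configurable via `alignment_params()`.
* **Identity.** `identity = matches / columns`, where columns counts match,
  mismatch *and* gap columns. This is the percent-identity convention of
  tabular alignment output, and it means indel-rich reads report lower
  identity than their substitution rate alone would suggest — deliberately,
  since downstream rules consume exactly this quantity.
* **Exact vs heuristic.** Pairs up to 2 kb per side are solved by exhaustive
  dynamic programming. Larger problems use 11-mer seeding: seed diagonals are
  collected, the densest band-wide diagonal window is banded-DP'd (half-width
  100 diagonals), and the band doubles until the traceback no longer touches
  a band edge. When no seeds exist and the pair is small, the heuristic falls
  back to the exhaustive DP, so on small inputs the two paths provably agree
  (this equivalence is a test).
* **Seed support.** A pair counts as seeded only when at least two k-mer
  seeds cluster within one band-wide diagonal window (a BLAST-two-hit-style
  filter), and `map_reads()` additionally requires a minimum alignment score
  of 50. Without these rules, chance 11-mers between unrelated
  multi-kilobase sequences would make every random read "map" with a
  trivial local alignment.
* **Coordinates.** All user-facing coordinates are 1-based inclusive
  (the IRanges/BLAST convention); reverse-strand hits are reported on the
  forward strand of both sequences with a strand column.
* **Adapter location** (`semiglobal_locate()`) is a separate primitive:
  unit-cost edit distance, full pattern anchored, text ends free. The edit
  budget for an adapter of length $L$ at error rate $r$ is
  $\lfloor rL \rfloor$ — a conservative reading of "error rate".
  Overlapping candidate matches reduce to locally minimal-edit,
  non-overlapping spans (fewest edits first, leftmost on ties).

## Read curation

`curate_read()` applies, in fixed order: (1) removal of 65 bases from both
read ends (the length of the amplification adapter); (2) an approximate
adapter scan at a platform-dependent error rate (20% for nanopore-grade
consensus reads, 5% for high-accuracy multi-pass reads); (3) chimera
calling; (4) a 150 bp minimum-length filter.

The chimera rule makes "internal adapter" precise: an adapter span with at
least `chimera_flank` (50 bp) of sequence on *both* sides marks the read as
a PCR fusion and the read is removed whole (not split). Spans closer than
the flank to an end are residue from the library chemistry and are trimmed
off instead, iteratively, since trimming an outer span can expose another.
Only a *full* adapter occurrence within the edit budget is detectable; a few
residual bases at a read end are below the information content of any
approximate matcher and are tolerated by design.

## On-target scoring

A read is on target when some bait aligns to it with at least 96 alignment
columns at 80% identity or better. "Over 96 bases" is interpreted as
alignment *columns* (gap columns included), matching a filter applied to
tabular alignment output; whether to count gapped columns was an open
convention and this choice is declared rather than inherited. The decision
is monotone: raising either threshold can only shrink the on-target set.

## Motif classification

Reads, contigs or proteins are classified `none` / `partial` / `complete`
by scanning six-frame translations (standard genetic code; codons containing
`N` become `X`; stops are rendered `*` and never spanned by a motif window)
for a configurable set of degenerate amino-acid motifs. The shipped defaults
are the canonical coarse NB-ARC/LRR consensus motifs — P-loop `GGVGKTT`,
Kinase-2 `LLVLDDVW`, GLPL `GLPLAL`, an MHD-class motif `xMHDx`, and the LRR
repeat `LxxLxxLxL`. The MHD core is only three residues, so it ships
wildcard-padded to meet the five-position minimum that keeps patterns
specific. These consensus patterns are placeholders for the richer
probabilistic motif models of dedicated NLR annotation tools; the classifier
is calibrated for synthetic data and configurability, not for reproducing
any specific tool's calls on real data.

A call is `complete` when one frame contains, in order, a P-loop hit, a
GLPL-class hit downstream of it, and at least two LRR hits downstream of
both; `partial` when any NB-ARC or LRR motif is hit anywhere. Requiring the
cassette within a *single* frame is what makes the classifier
frameshift-sensitive: a 1 bp indel between cassette motifs splits the
architecture across frames and demotes the call — the synthetic analogue of
indel-rich platforms depressing motif recognition, and a tested property.

## Assembly evaluation

`best_hit_search()` keeps at most one accepted hit per reference query (the
best-scoring local alignment across contigs and strands), mirroring a
max-target-seqs-1 search. Acceptance replaces e-value filtering with
explicit thresholds — at least 500 alignment columns at 85% identity —
because e-values depend on database size and tool internals and are not
reproducible quantities; the thresholds are configurable.
`dedupe_same_subject()` then removes hits whose subject intervals overlap an
already-kept hit by more than half of the shorter interval, the same-subject
hand-curation step of BLAST-style evaluations. Summaries report means and
*sample* (n−1) standard deviations — the spreadsheet default — of percent
identity, alignment length and query alignment-length percentage, plus
reference coverage. Self-evaluation of any reference is the identity case
(coverage 100%, identity 100 ± 0) and is asserted as a test.

## Novel-gene triage

The triage emulates rapid in-field novel-NLR discovery: map reads to a
*reduced* reference (the genes of interest withheld), compute the empirical
threshold

$$ T = \bar{x} - k \cdot s, \qquad k = 2 $$

over best-hit percent identities (sample SD; one best hit per mapped read;
unmapped reads do not enter the mean), and pool all unmapped reads with all
reads mapping below $T$ as candidates for reassembly. Candidates are
assembled — by an external long-read assembler in production, or by the
built-in fixture-grade greedy overlap assembler (`toy_assemble()`) at desk
scale — optionally filtered for NLR motifs, and scored against the withheld
genes with the acceptance criteria above.

### When the threshold rule works, and when it cannot

The mean − 2·SD rule assumes the novel-origin reads are a small minority of
the library. For error-free reads the best-hit identity distribution is a
two-point mixture: known-origin reads at exactly 100%, novel-origin reads at
$100 - d$ for divergence $d$. With novel fraction $p$,

$$ T = 100 - d\left(p + 2\sqrt{p(1-p)}\right), $$

and novel reads fall below $T$ only when $p + 2\sqrt{p(1-p)} < 1$, i.e.
$p < 0.2$ — *independent of the divergence*. At a realistic novel fraction
(a handful of fusion-domain genes against a several-hundred-gene reference,
$p \approx 0.06$) the threshold sits far above the novel reads' identity and
selection is essentially deterministic; that regime is exercised as a green
test. At $p$ near or above 0.2 (for example three novel genes against ten
known ones, $p = 3/13$) selection relies on per-read identity tail
fluctuations, and recovering *every* withheld gene becomes a lottery — the
corresponding end-to-end assertion in the acceptance suite is expected to be
fragile under exactly those conditions, and the published experiment this
mirrors likewise recovered only a subset (29 of 37) of its withheld genes.
This breakdown is a property of the statistic, not of the implementation.

## The simulator

`simulate_reference()`, `design_baits()`, `simulate_reads()` and
`spike_novel()` generate data with the statistical structure the pipeline
assumes, each stage under its own sub-seed of one configured seed
(byte-reproducible; stages can be regenerated independently):

* **Gene families.** Each family is a random stop-free ORF carrying the
  ordered motif cassette (P-loop, Kinase-2, GLPL, MHD, three LRRs) at fixed
  relative positions. The first paralog is the ancestral copy itself; further
  paralogs carry substitutions at the configured per-base divergence, so a
  two-paralog family sits at pairwise identity $1 - d$. Cassette positions
  are never mutated, emulating purifying selection on core motifs and
  guaranteeing every simulated gene classifies `complete` on clean input.
  Mutation counts are exact (`round(rate × length)`), so realized divergence
  equals the nominal rate.
* **Novel genes** derive from a randomly chosen existing gene at the
  configured divergence (default 12%) and are tagged withheld: present in
  the sample, absent from the reference handed to triage. Integrated-domain
  (fusion) structure is *not* modeled — novel genes are diverged paralogs —
  a simplification that leaves the identity-based triage mechanics
  unchanged.
* **Reads.** Read lengths are log-normal (default mode ≈ 2.8 kb, `sdlog`
  0.45), truncated to [200, 20000] bp; the sampled length is the read as a
  sequencer reports it, and the insert is what remains after the two 65 bp
  end adapters. Fragments are drawn per gene until the target coverage is
  met; a configurable fraction of reads is random off-target sequence; with
  the configured probability a read is a chimera of two fragments joined by
  the adapter. Per-base errors follow the platform profile — the
  nanopore-grade preset {3% substitution, 2% insertion, 4% deletion} is
  deliberately deletion-heavy, the indel-dominated profile that stresses the
  frameshift sensitivity of the motif classifier; the high-accuracy preset
  is {0.2%, 0.1%, 0.1%}. Quality strings are flat at the Phred of the
  profile's total error rate (no position-dependent quality model). A truth
  record per read carries source gene, coordinates, strand, chimera status
  and realized error counts.

What passing tests on this data do *not* show: behavior under
position-dependent quality, capture-efficiency bias, PCR duplication,
homopolymer-specific error structure, or real motif-model calibration.

## Numerical conventions and determinism

Percentages print half-up at two decimals (`format_pct()`), the spreadsheet
convention. Ties are deterministic everywhere: mapping ties break by higher
identity then lexicographically smallest subject id; modal statistics take
the smallest value on ties (modal accuracy is binned at two decimals on the
percent scale before the mode, modal length is unbinned); span reduction
prefers fewest edits, then leftmost; the toy assembler merges the
highest-scoring overlap with lexicographic tie-breaks and takes overlap
bases from the lexicographically smaller member. Reruns under one seed
produce byte-identical FASTQ, truth tables and reports.

## Problem sizes

The test and acceptance workloads are sized for a laptop-class run: 200
oracle-checked alignment pairs up to 500 bp, 200 adapter-search pairs at two
error rates, curation truth on ~500 reads with 10% chimeras at the nanopore
error profile, on-target truth on ~500 error-free reads with a 20%
off-target fraction, 100 simulated genes for the motif/frameshift property,
and triage experiments with 10–17 genes at 25–50× coverage with mode-1.4 kb
reads on 2.5–4 kb genes — the read:gene length ratio of the sequenced
libraries this emulates, scaled down. The full suite runs in a few minutes.

## Limitations

Base calling, signal-level polishing, production assembly (Canu/HGAP-class),
Illumina-based contig repair and de novo protein prediction are outside the
package: assembly is a documented hand-off (FASTQ in, contig FASTA out), and
`toy_assemble()` is fixture-grade by design — greedy, majority-vote-free for
pairs, and unsuitable for error-rich reads (overlaps below the 90% overlap
identity default simply never merge, which is the honest behavior for
uncorrected nanopore-grade data). The motif set is a coarse consensus
stand-in; calibration against a dedicated NLR annotation tool on real data
is future validation, not an assumption.
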