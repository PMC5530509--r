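# renseqr

Long-read RenSeq curation, capture assessment, NLR motif classification and
novel-gene triage, as a tested R package.

## The problem

Plant resistance genes mostly encode **NLR** immune receptors
(nucleotide-binding leucine-rich repeat proteins), which sit in clusters of
near-identical paralogs. **RenSeq** (resistance gene enrichment sequencing)
captures these loci with tiled biotinylated baits before sequencing; on
long-read platforms (Oxford Nanopore consensus reads, PacBio reads of
insert) the enriched libraries span whole genes but carry indel-rich errors,
amplification adapters on both read ends, and PCR-fusion chimeras joined by
adapter sequence. `renseqr` implements the bespoke computational stages of
such an experiment for anyone analysing targeted long-read capture data:

* **Read curation** — fixed 65 bp end trim, approximate adapter removal at a
  platform-dependent error rate (edit budget ⌊r·L⌋), a 150 bp length filter,
  and chimera removal: a read retaining a full adapter match with ≥ 50 bp on
  both sides is a PCR fusion and is dropped whole.
* **On-target scoring** — a read is on target when a bait aligns to it over
  ≥ 96 alignment columns at ≥ 80% identity.
* **Read/assembly QC** — N50, modal length, mapping-derived accuracy
  (identity = matches / all alignment columns, gaps included), best-hit
  evaluation of assemblies against an annotated reference with same-subject
  deduplication, and dot-plot match-segment export (≥ 500 bp matches).
* **NLR motif classification** — six-frame translation and degenerate motif
  scanning (P-loop, Kinase-2, GLPL, MHD-class, LRR defaults; fully
  configurable); a call is *complete* when one frame contains P-loop →
  GLPL → ≥ 2 LRRs in order, making the classifier frameshift-sensitive by
  construction.
* **Novel-NLR triage** — map reads to a reduced reference, take the
  empirical threshold *T = mean − 2·SD* of best-hit percent identity, pool
  all unmapped and below-threshold reads, reassemble them, and score
  recovery of the withheld genes.
* **A deterministic simulator** — paralog families with planted motif
  cassettes, tiled baits, log-normal read lengths (mode ≈ 2.8 kb),
  deletion-heavy nanopore-grade error profiles, adapters, chimeras,
  off-target reads, and a per-read ground-truth table.

The alignment engine (exact affine-gap local DP for small inputs, seeded
banded DP with band widening for large ones, semiglobal edit-distance
adapter location) is built into the package and oracle-tested against
independent implementations.

## Worked example

Simulate a small nanopore-style capture experiment and run the stages:

```r
library(renseqr)

cfg <- sim_config(seed = 42, n_families = 3, paralogs_per_family = 2,
                  novel_genes = 1, coverage = 8,
                  error_profile = error_profile("nanopore_2d"),
                  chimera_rate = 0.05, off_target_fraction = 0.2)
ref   <- simulate_reference(cfg)
known <- ref$genes[!ref$genes$id %in% ref$withheld_ids, ]
rr    <- simulate_reads(ref$genes, cfg)

cur <- curate_set(rr$reads, curation_config(
  adapters = list(adapter_spec("amplification", cfg$adapter, 0.20))))
cur$summary
#>   n_input n_kept n_removed_short n_removed_chimeric total_bases  n50 mean_length modal_length
#> 1      86     79               0                  7      218510 3266    2765.949         2033

ot <- on_target_rate(cur$kept, design_baits(known))
format_pct(ot$rate_pct, scale100 = TRUE)
#> [1] "79.75"

acc <- accuracy_stats(map_reads(cur$kept, known), nrow(cur$kept))
format_pct(acc$mean_accuracy)
#> [1] "90.19"

annotate_set(ref$genes)$summary$complete_of_hits_pct
#> [1] 100
```

Reading the numbers: 7 of 86 reads were removed as adapter-joined chimeras
(5% were planted); 79.75% of curated reads contain a bait match — the
planted off-target fraction was 20% — and the mapping-derived mean accuracy
of 90.19% reflects the planted ~9% indel-rich error profile (gap columns
count against identity). Every simulated reference gene carries its complete
motif cassette.

The novel-gene triage runs the same way (see `?run_triage`): withhold gene
ids from the reference, map, threshold at mean − 2·SD, assemble the
candidate reads and score recovery of the withheld genes.

A thin command-line wrapper over the same functions ships in
`inst/exec/renseq` (subcommands `simulate`, `curate`, `qc`, `ontarget`,
`motifs`, `eval`, `triage`, `run`).

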