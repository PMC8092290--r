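---
title: "Dual-locus CRISPR spacer acquisition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-locus CRISPR spacer acquisition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceracq)
```

## The problem

Some bacteria carry two CRISPR-Cas loci of different types in one genome:
here, a DNA-targeting subtype II-C array (with its own Cas1/Cas2
adaptation machinery) and an RNA-targeting subtype VI-B array that has no
adaptation genes of its own. After a phage challenge, both arrays gain
new spacers. Three questions drive the analysis this package implements:

1. **Where do new spacers come from?** Each spacer is mapped back to a
   protospacer on the phage or the host ("self") genome.
2. **What acquisition motif flanks the protospacers?** Both loci use the
   same spacer acquisition motif (SAM), `5'-NNNNNTAAA-3'`, read on the
   guide (crRNA-matching) strand — downstream of II-C protospacers and,
   as the reverse complement `TTTANNNNN`, upstream of VI-B protospacers.
3. **Do the two arrays draw from a shared prespacer pool?** If the VI-B
   locus acquires spacers in trans through the II-C machinery, the two
   unique spacer pools should be far more similar than sampling the phage
   genome at random (or even at random SAM sites) can explain. An excess
   also shows up as identical spacer sequences across loci.

A fourth question — whether an RNA-targeting locus prefers spacers whose
crRNA can actually bind mRNA — is answered with an exact binomial test
against an equal-strand null.

## Pipeline stages

`run_pipeline()` chains the stages; each is exported on its own and all
tabular results are tibbles.

1. **Read processing** (`extract_spacers()`): Phred+33 amplicon reads are
   quality-trimmed (trailing-quality cut at Q23, then a 5'→3' sliding
   window of 3 bases at mean Q21, then a 100 bp length floor) and the new
   spacer is taken as the 27–32 bases between an intact copy of the
   locus repeat and the first 4 bases of the next repeat. Spacers are
   emitted in crRNA orientation: the per-locus read orientation flag maps
   amplicon strand to guide strand, so every downstream motif statement
   is made once, in one frame.
2. **Clustering** (`cluster_spacers()`): greedy CD-HIT-style collapsing
   at 0.8 identity (word size 5) gives the *unique* pool; read-backed
   cluster sizes give the *absolute* view. Identity is the best ungapped
   offset alignment divided by the shorter length — an exactly
   reproducible, oracle-checkable definition.
3. **Mapping** (`hierarchical_map()`): each unique spacer is aligned
   ungapped and soft-clipped against the phage genome first, scored
   `2·matches − 6·mismatches` with acceptance threshold `10 + 8·ln L`
   (≈ 37.2 at L = 30); phage-unmapped spacers try the host; the rest are
   discarded. The hit strand is defined as the genome strand whose
   forward sequence equals the crRNA — the single convention that drives
   both SAM orientation and mRNA classification.
4. **Motif analysis** (`extract_flanks()`, `detect_sam()`,
   `build_pfm()`, `count_motif()`): 15 bp guide-oriented flanks; the SAM
   call is `TAAA` at downstream positions 6–9 for array-to-leader loci
   and `TTTA` at upstream positions 7–10 for leader-to-array loci. These
   two tests are exact reverse complements: the same genomic protospacer
   assigned the opposite guide strand flips between them, which the test
   suite verifies exhaustively.
5. **Target statistics** (`classify_mrna()`, `mrna_proportions()`,
   `bin_distribution()`): a spacer is mRNA-targeting iff its protospacer
   is fully inside an ORF *and* its guide strand is opposite the ORF
   strand; intergenic and boundary-straddling hits are excluded. Each
   (locus × genome × view) pool gets an exact one-tailed binomial test at
   p = 0.5, pool-size matched. Binned target distributions use 3 %-of-
   genome bins (midpoint assignment, the last bin absorbs the remainder)
   with a centred 5-bin moving average across replicates.
6. **Overlap null** (`run_null()`, `observed_overlap()`): the observed
   fraction of VI-B unique phage-targeting spacers with a ≥ 0.9-identity
   match in the II-C pool is compared with 1000 Monte-Carlo iterations
   that sample equally many 30-mers from the phage genome either at
   uniform random positions/strands or uniformly from SAM-adjacent
   placements. A normal distribution is fitted by maximum likelihood
   (sample mean, population standard deviation) and the one-tailed upper
   tail gives the headline p; a rank-based empirical p is always
   co-reported because the normal fit is an approximation.

## The synthetic-data generator

Because the analysis is defined on deposited deep-sequencing data, the
package ships a first-class generator (`generate_genome()`,
`simulate_acquisition()`, `emit_amplicon_reads()`) whose defaults encode
the emulated study conditions:

| dial | default | rationale |
|---|---|---|
| phage genome | 47 kb, GC 0.32, linear | phage-realistic size and AT content; linear ends are respected when flanks are extracted |
| host genome | 300 kb, circular | deliberately scaled down from chromosome scale to keep runs fast while leaving a realistic search space |
| SAM preference π | 0.63 | the observed fraction of phage-targeting II-C protospacers with the canonical SAM |
| spacer lengths | mass at 30 bp over 27–32 | the observed modal length |
| strand bias β | 0.5 | no net strand preference |
| self fraction σ | 0.05 | self-targeting is a small minority of events |
| hotspot | Gaussian at 0.85 of the genome, width 0.08, weight 0.6 | targeting concentrates at the genome end opposite the morphogenesis genes |
| shared pool ρ | 0.6 | reproduces inter-locus sharing at the observed level (~0.6 of the query pool) |
| read errors | sub 0.005, ins 0.001, del 0.002, homopolymer ×3 | Ion-Torrent-like profile |

Every event records its realised ground truth (genome, interval, guide
strand, SAM flank state, spacer, copy count), and every read id traces to
one event, so each stage can be scored against truth. Two modelling
choices deserve emphasis:

* **The SAM flag is the realised flank state.** At π = 0 a uniformly
  placed protospacer still lands next to a SAM by chance (~1–3 % on an
  AT-rich genome); recording the realised state (planted or incidental)
  is what makes "estimate within the binomial 99 % CI of truth" a
  well-posed recovery check at every π.
* **Shared events copy interval *and* guide strand.** A ρ-event in the
  second locus reuses a first-locus protospacer with its strand, so the
  two arrays hold identical spacer sequences — the observable that the
  0.9-identity cross-pool comparison measures. The locus's own
  (non-shared) SAM-planted events use its own motif side. Clustering
  deliberately does **not** compare reverse complements: spacers are
  already orientation-canonicalised, and folding strands together would
  conflate sense and antisense acquisition.

What the generator does **not** emulate: PCR chimeras and barcode
demultiplexing, phage population evolution, interference/selection
feedback on the acquired pools, antisense or intergenic transcription.
Passing tests therefore demonstrate pipeline correctness under a clean
acquisition model, not robustness to every artefact of real libraries.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere inside the package;
  conversion happens only at I/O boundaries (GFF3/GenBank are 1-based
  inclusive). `N` bases never match anything — not even another `N` — in
  identity, alignment or motif scans.
* **Trimming order** is trailing-cut before sliding-window, then the
  length floor; the order is fixed so results are bit-reproducible.
* **Anchor search is longest-first.** When locating the 4-base repeat
  anchor 27–32 bases downstream of the first repeat, lengths are tried
  from 32 down to 27. A true spacer whose own suffix happens to end with
  a prefix of the anchor would be silently truncated by a shortest-first
  scan, while a false *extension* would require the anchor to recur
  inside the repeat itself, which the default repeats do not do.
* **Greedy clustering order** is (count desc, length desc,
  lexicographic), replacing file order so that permuting input reads
  cannot change the pools.
* **Alignment is ungapped** (a deliberate simplification: spacers are
  27–32 bp and acquisition introduces no indels), with ties broken by
  fewer mismatches, then smaller genome start, then `+` before `-`. The
  Kadane-style scan resets on non-positive running scores, which provably
  surfaces the fewest-mismatch window among equal-score windows at each
  end position; equivalence with an exhaustive
  (position × strand × sub-span) search is asserted in the tests.
* **Multi-mapping**: only the single best hit is reported under the tie
  rule above, so downstream statistics are deterministic.
* **Direction of one-tailed tests** is an explicit argument; `"auto"`
  picks the side of the observed proportion and records it in the output,
  never silently.
* **Degenerate null fits** (σ = 0) report p as 0 or 1 with a warning
  rather than failing.
* **Both SAM-site scopes are exposed.** Genome-wide and CDS-restricted
  motif counts (and strand splits under both the reporting convention
  and per-ORF labels) are emitted side by side, because the two scopes
  answer slightly different questions and either may be wanted as the
  site list for PAM-adjacent sampling.

## Known limitations

* **Indel-bearing reads form artefact clusters.** Because clustering
  identity is ungapped, a read with an insertion or deletion inside the
  spacer can found its own unique cluster instead of being absorbed into
  its parent (a gapped clusterer would merge it). Under the default
  Ion-Torrent-like error model this inflates unique pools by roughly
  5–10 % and dilutes motif rates accordingly. The parameter-recovery
  checks therefore run the generator with a substitution-only error
  model; recovering dials under indel noise would require gapped
  identity, which is out of scope by design.
* The aligner reimplementation is not the original heuristic local
  aligner; published discard rates depend on that aligner's internals
  and are not promised by the ungapped scan (the deviation is stamped in
  output metadata via the config hash and version line).
* mRNA classification trusts predicted ORFs and ignores antisense and
  intergenic transcription, so RNA-targeting counts are lower bounds.

## Problem sizes used by the shipped checks

The test suite and the acceptance script choose sizes that keep the full
run comfortably on one CPU while leaving every statistic well resolved:
oracle equivalences run on 1.2–8 kb genomes and pools of ≤ 50 sequences
(100 seeded pools); parameter recovery uses 300 events per locus on a
20 kb phage / 30 kb host; null calibration uses 200 seeded draws of 100
spacers against a 300-sequence genome-derived reference with 200
iterations per draw (sizes picked so the empirical p's intrinsic
discreteness stays well inside the Kolmogorov–Smirnov α = 0.01 band);
the acceptance script itself runs the full 47 kb / 300 kb conditions
with 1000 null iterations.

## A worked example

```{r example, eval = FALSE}
params <- acquisition_params(n_events = c(1000, 500))
ds <- simulate_dataset(seed = 1, params = params)
cfg <- run_config(loci = ds$loci, seed = 1)
report <- run_pipeline(cfg, phage = ds$phage, host = ds$host,
                       reads = ds$reads)
report                      # stage summaries
report$sam_rates            # SAM rate per locus over phage hits
glance(report$overlap$random)
autoplot(report$overlap$pam_adjacent)
autoplot(report$pfms[[1]])  # downstream-flank information logo
```

The README shows the numbers such a run prints and how
`scripts/acceptance.R` re-derives them from scratch.
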