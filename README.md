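# spaceracq

Analysis of CRISPR spacer acquisition in a dual-locus system: a
DNA-targeting subtype II-C array (which owns the Cas1/Cas2 adaptation
machinery) co-occurring with an RNA-targeting subtype VI-B array that has
none of its own. After a phage challenge both arrays gain new spacers;
this package asks where those spacers come from, what acquisition motif
flanks them, whether the two arrays draw on a shared prespacer pool (in
trans adaptation), and whether an RNA-targeting locus is biased toward
spacers whose crRNA can bind mRNA.

## What it computes

Starting from CRISPR-array amplicon reads (FASTQ, Phred+33), genome
FASTA files and ORF annotations (GFF3 or a flat CDS table), the pipeline

1. **extracts new spacers** with the repeat-anchored rule: quality trim
   (trailing Q23, sliding window 3/Q21, length ≥ 100), then the 27–32 bp
   between an intact repeat and the first 4 bases of the next repeat,
   emitted in crRNA orientation;
2. **collapses them into unique pools** by greedy CD-HIT-style
   clustering at identity ≥ 0.8 (word size 5), with identity defined as
   the best ungapped offset alignment over the shorter sequence — read
   counts give the parallel "absolute" view;
3. **maps each unique spacer** hierarchically (phage first, then host,
   else discarded) with an ungapped soft-clipped local aligner scored
   `2·matches − 6·mismatches` and accepted at `score ≥ 10 + 8·ln L`;
4. **infers the spacer acquisition motif (SAM)** from 15 bp
   guide-oriented flanks: `5'-NNNNNTAAA-3'` downstream of II-C
   protospacers and its reverse complement `TTTANNNNN` upstream of VI-B
   protospacers — two views of one genomic motif, plus position
   frequency matrices, information content, and genome-wide /
   CDS-restricted motif counts with strand splits;
5. **tests mRNA-targeting bias**: a hit is mRNA-targeting iff it lies
   fully inside an ORF with its guide strand opposite the ORF strand;
   each pool gets an exact one-tailed binomial test against
   `k ~ Binomial(n, 0.5)` (computed by log-space summation), with the
   expected 95% interval from exact binomial quantiles;
6. **quantifies inter-locus pool sharing**: the fraction of VI-B unique
   phage-targeting spacers with a ≥ 0.9-identity match in the II-C pool,
   compared against 1000 Monte-Carlo samplings of equally many 30-mers
   from the phage genome (uniform positions, or PAM-adjacent sites
   only); a maximum-likelihood normal fit `(μ̂, σ̂)` of the simulated
   overlap fractions gives the one-tailed upper-tail p, co-reported with
   a rank-based empirical p;
7. also emits **3%-of-genome binned target distributions** per strand
   and replicate with a smoothed across-replicate mean and a motif
   frequency track.

A first-class synthetic-data generator (`generate_genome()`,
`simulate_acquisition()`, `emit_amplicon_reads()`) simulates acquisition
with tunable SAM preference, strand bias, self-targeting fraction,
positional hotspots, a shared prespacer pool between the loci, and
Ion-Torrent-like read errors — with full ground truth, so every stage is
testable without external data.

## Worked example

```r
library(spaceracq)

params <- acquisition_params(n_events = c(200, 120))   # II-C, VI-B events
ds  <- simulate_dataset(seed = 42, params = params,
                        phage_length = 20000, host_length = 40000)
cfg <- run_config(loci = ds$loci, seed = 42,
                  null_model = null_model_config(n_iterations = 200, seed = 42))
report <- run_pipeline(cfg, phage = ds$phage, host = ds$host, reads = ds$reads)
report
#> <pipeline_report> spaceracq 0.1.0, seed 42, config c3636d8110b3dc2d0db34ae4ec28788d
#> # A tibble: 2 × 5
#>   locus_id reads_in trimmed_out no_spacer extracted
#> 1 II-C          684           0       196       488
#> 2 VI-B          382           0       122       260
#> # A tibble: 2 × 6
#>   locus_id n_input n_phage n_self n_discarded discard_fraction
#> 1 II-C         189     159     12          18           0.0952
#> 2 VI-B         105      98      3           4           0.0381
#> overlap: observed 0.408 | null random mu 0.025 sd 0.015 | pam mu 0.164 sd 0.038

report$sam_rates
#>   locus_id n_phage_hits sam_rate
#> 1 II-C              159    0.553
#> 2 VI-B               98    0.306

glance(report$overlap$random)
#>   mode       mu  sigma observed  p_normal p_empirical n_iterations sample_size
#> 1 random 0.0249 0.0153    0.408 6.78e-139     0.00498          200          98
```

Reading these numbers: of 189 unique II-C spacers, 159 map to the phage
and 12 to the host ("self"); 55% of II-C phage protospacers carry the
canonical SAM (the simulation planted 63% before error-bearing reads
dilute the unique pool). 40.8% of VI-B phage-targeting spacers have a
≥ 0.9-identity match in the II-C pool, while random genome sampling
explains only 2.5 ± 1.5% — upper-tail p ≈ 7e-139 under the fitted
normal, i.e. the two loci share a prespacer pool far beyond chance
(the run simulated a shared-pool fraction of 0.6).

Every result type has `tidy()`/`glance()` methods and an `autoplot()`
(overlap-null histograms with the fitted normal, flank information
logos, binned target distributions), plus `plot_mrna_proportions()` for
the binomial-test table.

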