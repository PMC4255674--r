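# inseqr

Insertion-sequencing (INSeq / Tn-seq) analysis for *mariner*-transposon mutant
libraries in multi-replicon bacterial genomes, with four-class gene
essentiality calling by a hidden Markov model.

## The problem

A *mariner* (himar1) transposon inserts exclusively at TA dinucleotides, so a
genome's possible insertion sites can be enumerated exactly. Sequencing the
transposon–genome junctions of a saturating mutant pool after growth under a
condition of interest yields a read count for every TA site; genes whose
disruption removes cells from the pool show up as stretches of empty sites,
and genes whose disruption helps growth accumulate excess reads. `inseqr`
takes raw reads (or its own simulator's output) to per-replicon saturation
statistics and per-gene phenotypic calls. It is aimed at microbial
geneticists running saturating transposon screens — in rhizobia and other
multi-replicon organisms in particular, where plasmid copy number skews read
depth between replicons.

The pipeline:

1. **TA-site enumeration** — every position `p` with `seq[p..p+1] == "TA"`,
   per replicon.
2. **Tag extraction** — 3′ quality trimming to Q20, location of the 27 bp
   inverted repeat that ends the 53 bp transposon prefix, then the following
   15–16 bp genomic tag, which must begin `TA`.
3. **Exact unique mapping** — a hash of every TA-anchored 15/16-mer on both
   strands; zero mismatches, multi-mappers discarded; per-site read counts.
4. **Saturation statistics** — insertion density (occupied/potential sites),
   mean and median read count over occupied sites, per replicon and pooled.
5. **Essentiality HMM** — states ES/GD/NE/GA with geometric emissions
   `P(c|s) = p_s (1-p_s)^c`, `p_s = 1/(1+μ_s)`, fitted per replicon
   (`μ_NE = m`, the occupied-site mean; `μ_GD = m/10`; `μ_GA = 5m`;
   `μ_ES = 0.01`), sticky transitions (0.98 self), Viterbi-decoded over all
   sites. A gene's class is the modal state of its sites (ties break toward
   severity), with an extreme-value override: a gene is essential if its
   longest ES run is longer than chance allows,
   `P(R ≥ r) ≈ 1 − exp{−(n−r+1)(1−p)p^r}`, tested family-wise across the
   replicon's genes.
6. **Simulator** — deterministic synthetic experiments (genome, GFF3,
   ground-truth classes, per-site counts, raw FASTQ) at the saturation level
   this assay achieves in practice (83% occupancy, ~19 reads per occupied
   site), for end-to-end validation.

See `vignettes/inseq-methods.Rmd` for the model, parameter rationale, and
limitations.

## Worked example

Simulate a small two-replicon experiment and run the full pipeline:

```r
library(inseqr)

cfg <- sim_config(seed = 42L, replicon_lengths = c(60000L, 20000L),
                  read_error_rate = 0.005)
sim <- simulate_counts(simulate_genome(cfg))
write_sim_genome(sim, "genome.fasta", "genes.gff3")
simulate_reads(sim, "reads.fastq")          # 46,823 reads

run_pipeline(pipeline_config(genome = "genome.fasta",
                             annotation = "genes.gff3",
                             reads = "reads.fastq",
                             out_dir = "out"))
```

The run log reports the attrition chain and headline results:

```
loaded 2 replicon(s), 80000 bp total
potential insertion sites: 3194
annotated genes: 76
reads: 46823 in; 0 quality-failed; 5996 without IR; 0 bad length; 380 without leading TA; 40447 tags
mapped: 37881 unique; 0 multi-aligned omitted; 2566 failed to align
overall insertion density: 0.75
gene classes: ES 6 | GD 2 | NE 68 | GA 0 | NoData 0
```

(The reads lost at the IR, leading-TA and alignment steps are the ones the
0.5% per-base error rate corrupted in the corresponding read segment.)

`out/replicon_summary.tsv` is the saturation table — one row per replicon
plus the pooled genome row (density = observed/potential sites; mean/median
over occupied sites; the genome mean/median follow the mean-of-means /
median-of-medians table convention, with the pooled mean alongside):

```
replicon_id  size_bp  gc_percent  gene_count  potential_sites  observed_sites  insertion_density  mean_read_count  median_read_count  mean_read_count_pooled
sim01        60000    60.99       57          2298             1753            0.76               15.18            10                 15.18
sim02        20000    58.09       19          896              647             0.72               17.43            12                 17.43
Genome       80000    60.26       76          3194             2400            0.75               16.3             11                 15.78
```

`out/gene_classes.tsv` holds the per-gene calls; an essential gene looks like
row `sim01_00004` — 41 TA sites, none inserted, a genome-wide-significant ES
run:

```
locus        replicon_id  phenotypic_class  n_sites  insertion_density  mean_read_count  modal_state  es_run_length  es_run_significant
sim01_00001  sim01        NE                38       0.868              16.424           NE           0              FALSE
sim01_00004  sim01        ES                41       0                  0                ES           41             TRUE
```

Comparing the calls with the simulator's `truth.tsv` gives 97.4% agreement on
this example (74/76 genes; the two misses are growth-defective genes called
essential — the intrinsically depth-limited distinction).

A command-line front end with per-stage subcommands
(`simulate | ta-sites | process-reads | map | stats | hmm | classify | report`)
is installed at `system.file("cli", "inseq.R", package = "inseqr")`.

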