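---
title: "Methods: saturating INSeq analysis with a four-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturating INSeq analysis with a four-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inseqr)
```

## The experiment this package analyses

A *mariner*-class (himar1) transposon inserts exclusively at TA dinucleotides.
That defined insertion preference makes saturating mutagenesis quantifiable:
the genome's TA sites can be enumerated *in silico*, a large pooled mutant
library covers most of them, and sequencing transposon--genome junctions
("Tn-tags") measures the abundance of every insertion after growth under a
condition of interest. Genes whose disruption kills or slows the cell are
visible as stretches of TA sites with no, or few, reads; genes whose
disruption helps the cell accumulate excess reads.

The MmeI-adapted construct targeted here produces single-end reads laid out as
53 bp of transposon sequence -- the last 27 bp being the inverted repeat (IR)
-- followed by 15--16 bp of adjacent genomic DNA (MmeI cuts 20/18 nt away from
its recognition site, hence the one-base ambiguity) and library adapter, on a
187 bp template. `read_structure()` carries these constants, shared by the tag
extractor and the read simulator.

The pipeline stages, each independently callable and orchestrated by
`run_pipeline()`:

1. **TA-site enumeration** (`ta_site_index`): every position whose base is `T`
   with an `A` next is a potential insertion site; overlapping occurrences in
   `TATA` runs all count, positions involving ambiguity codes do not.
2. **Tag extraction** (`process_fastq`): 3' quality trimming to Q20 (classic
   partial-sum rule: cut where the running sum of `floor - q` from the 3' end
   is maximal), exact IR location, the following 15--16 bases as the tag,
   which must begin `TA` -- the motif the transposon sat in. Attrition is
   reported per category and conserves the read count.
3. **Mapping** (`build_tag_index`, `map_tags`): zero mismatches, unique
   placement. Every genomic 15/16-mer starting at a TA site, on both strands
   reading away from the site, is hashed; a tag maps iff it equals a context
   seen at exactly one site. Tags matching several sites are discarded as
   multi-mappers, mirroring the *report unique alignments only* convention.
   A 16-mer with no entry is retried as its 15-mer prefix (the MmeI length
   ambiguity). For fixed-length exact lookups a k-mer table is faster and
   strictly more predictable than a general-purpose aligner, and removes a
   runtime dependency.
4. **Saturation statistics** (`summarize_replicon`, `summarize_genome`):
   insertion density (occupied / potential sites) and read-count moments over
   occupied sites, per replicon and pooled.
5. **Essentiality calling** (`classify_genome`): the HMM below, decoded per
   replicon, then per-gene classification.

## The hidden Markov model

Per-site read counts `c_i >= 0` along the ordered TA sites of one replicon are
modelled by a 4-state HMM with states ES (essential), GD (growth-defective),
NE (neutral), GA (growth-advantage) and geometric emissions

$$P(c \mid s) = p_s (1 - p_s)^c, \qquad p_s = \frac{1}{1 + \mu_s},$$

so `mu_s` is the expected read count in state `s`. Decoding is the Viterbi
algorithm in log space over all sites of the replicon, ignoring gene
boundaries; ties break toward the earlier state in the order ES, GD, NE, GA.

### Parameters and why

* **Neutral mean** `mu_NE = m`, the observed mean read count over occupied
  sites of that replicon. Fitting per replicon is essential: plasmids kept at
  higher copy number are sequenced proportionally deeper, and anchoring each
  replicon on its own `m` cancels depth out of the classification (verified by
  test: doubling a profile leaves every call unchanged).
* **Growth-defective mean** `mu_GD = m / 10`, **growth-advantage mean**
  `mu_GA = 5 m`: an order of magnitude below, and several-fold above,
  expectation.
* **Essential mean** `mu_ES = 0.01`, a near-zero constant rather than a
  fraction of `m`. Insertions in essential genes are *lost from the pool*, so
  their expected read count does not scale with sequencing depth. This choice
  matters quantitatively: an essential mean of `m/100 ~ 0.2` at typical depth
  puts 16% of the essential state's emission mass on non-zero counts, which
  makes essential stretches statistically close to zero-inflated
  growth-defective ones and measurably collapses the ES/GD separation in
  recovery experiments.
* **Transitions**: sticky, 0.98 self-transition, remaining 0.02 spread evenly.
  Genes span tens of TA sites, so state runs of that order are the prior
  expectation; 0.98 implies a mean run of 50 sites. With these emissions a
  run of about four consecutive empty sites is needed before the decoder
  leaves NE for ES, which sets the method's spatial resolution.
* **Initial distribution**: uniform.

All of these are overridable through `hmm_params()`.

`fit_emission_params()` refuses profiles with fewer than 100 sites or below 1%
occupancy: below that the library is not saturating and state calls would be
noise.

### From sites to genes

A gene's class is the modal Viterbi state over the TA sites lying fully inside
it (a site at the gene's last base extends one base beyond it and does not
count). Ties break toward severity, ES > GD > GA > NE: when the evidence is
balanced the conservative report is the fitness effect. Genes containing no TA
site cannot be assayed by a mariner transposon at all and are reported
`NoData`.

One override exists, for essential genes only: a gene whose longest run of
ES-decoded sites is longer than chance allows is called ES even if most of its
sites decode otherwise. This recovers essential genes whose termini tolerate
insertions (a common observation: the first/last few percent of an essential
open reading frame often accept disruption).

### The extreme-value run test

The longest success run `R` in `n` independent Bernoulli(`p`) trials follows,
asymptotically, a Gumbel law; the usable tail form is

$$P(R \ge r) \approx 1 - \exp\{-(n - r + 1)(1 - p)\, p^r\},$$

the expected number of start positions for such a run times its per-start
probability, exponentiated. The `n - r + 1` start count (rather than `n`)
matters precisely when `r` is a sizeable fraction of `n` -- an essential
stretch inside a short gene -- and is what keeps the approximation within a
few percent of the exact run-length distribution (computed by dynamic
programming in the test suite) across `n <= 50`, `p <= 0.3`, `r >= 5`.

Two calibration choices deserve explanation:

* **The null probability `p`** is the replicon-wide fraction of *empty* (zero
  read) sites. The hypothesis being rejected is "this gene is neutral and its
  ES-looking stretch is chance", and under that null the chance event is a
  run of sites that merely look uninserted -- which happens with the empty-site
  frequency (about 0.17 at 83% saturation). Using instead the fraction of
  sites *decoded* ES would be anti-conservative in a self-defeating way: the
  rarer ES decodes are, the smaller that fraction, and the "more significant"
  any short run becomes -- a replicon of purely neutral genes would flag its
  own chance zero-runs.
* **Multiplicity**: the override is tested once per annotated gene, several
  hundred to several thousand tests per replicon. At a per-gene 0.05 that
  guarantees dozens of false essentials, so `classify_replicon()` spends its
  `alpha` family-wise (Bonferroni, `alpha / n_genes`). With both choices a
  simulated replicon of purely neutral genes yields zero false fitness calls,
  while fully and partially uninserted essential genes are still recovered.

## The synthetic-data generator

`sim_config()` defaults describe a near-saturating mutagenesis of a
multi-replicon alpha-proteobacterial genome grown on rich medium:

| quantity | default | basis |
|---|---|---|
| replicons | 450 kb + 80 kb | desk-scale stand-ins for a chromosome plus a smaller plasmid |
| GC fraction | 0.61 / 0.58 | rhizobial genome composition |
| gene density | 0.95 per kb | ~7,350 genes on 7.75 Mb |
| class mix ES/GD/NE/GA | 5.6 / 4.0 / 89.9 / 0.5 % | reported class distribution of such libraries |
| neutral site occupancy | 0.83 | observed genome-wide insertion density |
| reads per occupied site | 19.4 (mean) | observed mean read count |
| copy-number factor | 1.14 on the small replicon | elevated plasmid copy number: deeper reads, same density |
| per-base error | 0.005 | small substitution-only error floor |

Genes are tiled regularly (80% coverage, alternating strands) and assigned
true classes i.i.d. from the mix. Per TA site, occupancy is Bernoulli with a
class-specific probability (ES 0; GD 0.4x target; NE/GA target) and occupied
sites draw a shifted-geometric count (minimum 1) with class-specific mean (GD
0.1x, NE 1x, GA 5x), scaled by the replicon's copy-number factor. Intergenic
sites behave as neutral -- saturated flanks are what make the decoder's
context informative at gene boundaries. Essential genes carry exactly zero
insertions by default; `es_edge_permissive = TRUE` lets their terminal 10% of
sites leak sparse low-count insertions to stress the run-based override.
`simulate_reads()` then emits the full read anatomy with constant Q37
qualities and uniform substitution errors.

Determinism is strict: one master seed, with per-replicon, per-stage
substreams derived arithmetically, so identical configs give byte-identical
FASTA/GFF3/FASTQ/truth files and adding a replicon does not perturb earlier
ones.

What the generator does *not* emulate: indel errors (relevant to
semiconductor sequencing), library-prep biases beyond copy number,
positional insertion bias, overlapping genes, and any growth dynamics -- read
counts are drawn per site, not per clone lineage. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under the
stated generative model, not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF3/WIG convention); a TA
  site's coordinate is its T. BED exports convert to 0-based half-open.
* Sites containing `N` are excluded (unmappable); circular replicons are
  treated as linear (at most one site per origin is affected).
* A site in two overlapping genes contributes to both classifications.
* Viterbi ties resolve to the earlier state (ES first): deterministic and
  conservative.
* The run-test null probability is clamped into the open unit interval for
  degenerate all-empty/all-occupied profiles; a run of length zero is never
  significant.
* Replicon summaries with no occupied sites report missing means/medians;
  zero potential sites report missing density.
* Reported tables round densities and read-count moments to 2 decimals; full
  precision is retained internally and in the JSON report. The genome summary
  row follows the field's table convention -- unweighted mean of replicon
  means, median of replicon medians -- with the occupancy-weighted pooled mean
  emitted alongside as the statistically conventional quantity.
* Simulation-based tests in the suite use 60--530 kb genomes (roughly 500
  genes at full scale, 3 replicate libraries for recovery measurements) --
  sizes chosen so the whole suite exercises every stage, including ~70,000
  simulated reads through the full read-processing path, in a few minutes on
  one core.

## Known limitations

* ES/GD discrimination is intrinsically depth-limited: a growth-defective
  gene at 10x-reduced representation and 40% of target occupancy shows many
  chance zero-runs, and some of its decodes are statistically
  indistinguishable from essential. In recovery experiments a minority of GD
  genes (roughly a quarter to a third at these defaults) are called ES; deeper
  sequencing, not a different statistic, is the remedy.
* Single-condition saturation analysis only: no input/output pool comparison,
  no Baum--Welch re-estimation, no Bayesian gene-level posterior.
* The mapper is exact by design; reads whose tag contains any sequencing
  error in its first 15 bases are lost rather than rescued, so the uniquely
  mapped fraction falls geometrically with the per-base error rate (at 1%
  error, about 65% of reads survive the 27 bp IR + 16 bp tag gauntlet, in
  close agreement with the closed form `(1-e)^27 ((1-e)^16 + e(1-e)^15)`).
* No paired-end support, no barcode demultiplexing, no GenBank flat files
  (convert to FASTA + GFF3 first).
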