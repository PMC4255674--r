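rlv3841_replicon_summary.tsv
  Published per-replicon saturation statistics for a near-saturating mariner
  (pSAM_Rl) insertion-sequencing mutagenesis of Rhizobium leguminosarum bv.
  viciae 3841 grown on TY medium: replicon size, GC%, annotated gene count,
  potential TA insertion sites, observed inserted sites, insertion density,
  and mean/median read count over occupied sites. The Genome row is the
  published combined row (site columns summed; density pooled; mean/median
  are the unweighted mean of replicon means / median of replicon medians).

rlv3841_class_summary.tsv
  Published per-replicon gene counts by phenotypic class (ES essential,
  GD growth-defective, NE neutral, GA growth-advantage, NoData = gene has no
  TA motif) plus mapped read counts, for the same experiment.

Both tables are transcriptions of published summary tables; the raw reads
were not deposited, so these serve as reference inputs for internal
arithmetic checks of the reporting layer.
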