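Package: inseqr
Title: Insertion Sequencing (INSeq) Analysis with HMM Essentiality Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mariner-transposon insertion sequencing (INSeq/Tn-seq)
    experiments in multi-replicon bacterial genomes. Enumerates TA dinucleotide
    insertion sites, extracts and maps MmeI-style 15-16 bp transposon junction
    tags with a zero-mismatch unique-placement rule, computes per-replicon
    saturation statistics (insertion density, read counts per occupied site),
    and assigns each annotated gene one of four phenotypic classes (essential,
    growth-defective, neutral, growth-advantage) by Viterbi decoding of a
    four-state hidden Markov model over per-site read counts, with an
    extreme-value longest-run test for essential stretches. Includes a
    deterministic synthetic-data generator (genome, annotation, insertion
    profiles, raw reads) so the complete pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
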