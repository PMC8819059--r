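Package: pepScore
Title: Evidence-Integrated Scoring of lncRNA-Encoded Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls open reading frames on long noncoding RNA transcripts
    using ATG and near-cognate start codons, maps six classes of
    translational evidence (Ribo-seq coverage, translation initiation
    sites, 3' UTR m6A sites, Pfam domain hits, CPAT and CPC2 coding
    probabilities) onto the called ORFs, computes median-normalized
    per-evidence and composite peptide-encoding scores, and classifies
    high-confidence peptides under species-specific evidence rules.
    Includes a deterministic simulator that plants ORFs and evidence
    tracks with known truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
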