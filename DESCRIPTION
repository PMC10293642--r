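Package: codonkit
Title: Codon Usage, Codon Context, and Codon Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing codon usage in protein-coding transcripts:
    nucleotide and positional composition, relative synonymous codon usage
    (RSCU) with over/under-representation classification, codon adaptation
    index (CAI), Wright's effective number of codons (ENc) with the
    ENc-GC3 expected curve, scaled chi-square bias, GRAVY and aromaticity
    protein indices, parity-rule-2 (PR2) coordinates, length-adjusted rare
    codon detection, codon-pair counting with adjusted-residual context
    classification, RSCU-based principal component analysis, and a seeded
    synthetic coding-sequence generator for validating every stage without
    external downloads. Per-gene reports mirror the tabular outputs used in
    comparative codon-usage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
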