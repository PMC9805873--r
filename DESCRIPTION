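Package: crisprispec
Title: Specificity Analysis for CRISPRi Guide RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses the genome-wide specificity of CRISPR interference
    (CRISPRi) guide RNAs. Enumerates candidate protospacer binding sites on
    both strands of a genome under a seed/non-seed mismatch ("flaw") budget
    with an exact PAM requirement, annotates sites by proximity to
    transcription start sites, cross-references proximal genes against
    differential-expression calls, attributes candidate off-target effects
    using a target-matched siRNA orthogonal control, checks for repressive
    spreading around the on-target locus, and provides the small readout
    computations (delta-delta-Cq relative expression, control-normalized
    readouts) used alongside such screens. A synthetic-data module generates
    genomes, guide tables, TSS tables and differential-expression tables
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
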