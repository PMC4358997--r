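Package: cryptsplice
Title: Detection and Sequence Characterization of Cryptic 3' Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting cryptic 3' splice sites that
    are preferentially used in SF3B1-mutant transcriptomes and for
    characterizing their sequence context. Reads STAR-style splice-junction
    count tables and a GTF annotation, classifies junctions as annotated or
    novel, tests each junction for differential usage between mutant and
    wild-type samples with a beta-binomial likelihood-ratio test that
    controls for gene-level expression and cancer type, pairs novel
    acceptors with their associated canonical 3' splice sites, scores
    candidate branch points with a position weight matrix, computes
    3'-intron nucleotide profiles and adenine enrichment, and quantifies
    cryptic-site usage as percent spliced in (PSI). Includes a synthetic
    splice-junction data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
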