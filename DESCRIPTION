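Package: rdnafoot
Title: Phylogenetic Footprinting of Tandemly Repeated rDNA Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting conserved, potentially functional elements
    in the intergenic spacer (IGS) of tandemly repeated ribosomal DNA by
    phylogenetic footprinting. Provides repeat-unit reconstruction from
    high-coverage assembly contigs with in-silico digestion and PCR
    validation, reference projection of multiple sequence alignments,
    sliding-window similarity tracks, a two-state phylogenetic hidden Markov
    model (conserved/nonconserved, REV substitution model, Felsenstein
    pruning) for conservation segmentation, outgroup mapping of conserved
    regions by local alignment, intersection of conserved regions with
    functional feature tracks (transcripts, CAGE peaks, chromatin states,
    small-RNA coverage) including transcription-associated zone calling, and
    a full synthetic-data generator with known ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
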