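Package: coreframe
Title: Core-Gene Framework Guided Scaffolding of Prokaryote Draft Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-assisted scaffolding of bacterial draft assemblies using
    the genome organizational framework defined by single-copy core genes.
    Order-conserved runs of core genes (syntenic segments) are extracted from a
    panel of complete reference genomes, draft contigs are ordered and oriented
    by the segments they carry, adjacencies are confirmed and extended with
    paired-end read links through a confidence-weighted contig-end graph, and a
    circular pseudo-genome is emitted following the most prevalent reference
    segment permutation that does not conflict with the observed assemblies.
    Includes a synthetic pangenome simulator and a truth-based evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
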