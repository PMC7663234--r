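Package: spliceomiR
Title: Segmental Classification and Comparative Analysis of Spliceosome-Fraction miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing small-RNA sequencing reads that map to miRNA
    hairpin precursors in nuclear spliceosome fractions. The package parses
    miRBase-style GFF3 annotations, builds per-hairpin segment maps (mature
    5p/3p, undefined complement, extension), classifies aligned reads into
    segmental categories, quantifies miRNA expression across replicated cell
    line groups with presence filtering and RPM normalisation, and implements
    a comparative layer: three-set Venn partitions of presence sets,
    Up/Down/Same expression-trend discretisation, genomic cluster-neighbour
    detection, and literature-consistency scoring. A synthetic-data generator
    with full ground truth supports end-to-end testing without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
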