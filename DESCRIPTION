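Package: tadreg
Title: Peak Clustering, Annotation and TAD-Scoped Regulatory Analysis for ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative chromatin analysis linking ChIP-seq peak classes to
    co-factor occupancy, genomic features, retrotransposon composition and
    regional (TAD-scoped) differential gene expression. Provides interval
    readers for BED/narrowPeak/bedGraph and tabular gene, TAD and repeat
    annotations; windowed multi-track signal matrices and k-means peak
    clustering with per-cluster tag-density profiles; summit-based genomic
    feature classification and IUPAC consensus motif scanning; spectral-count
    interactor filtering for RIME proteomics; distance-bracket hypergeometric
    peak-gene association with random-gene controls; TAD containment analyses
    (directional expression proportions, co-localization permutation test,
    boundary-distance test, adjacent-TAD distance-mirror control); and a
    seeded synthetic-data generator that produces a complete, internally
    consistent dataset bundle with planted structure so that every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
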