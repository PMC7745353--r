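Package: txclip
Title: Transcript-Aware Annotation and Context Extraction for CLIP-Seq Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for CLIP-seq peak regions that takes the
    spliced transcript into account. Maps binding-site intervals between
    genomic and spliced-transcript coordinates, selects one representative
    (most prominent) isoform per gene from Ensembl-style annotation using the
    APPRIS / transcript-support-level / GENCODE-basic hierarchy, classifies
    sites by exon overlap, detects exon-border and adjacent-exon pair sites,
    extracts fixed-width genomic and transcript sequence context around site
    centers, scans both context sets for IUPAC motifs with bounded spacers
    (including motifs split across splice junctions), samples negative sites
    for classifier training, and computes dataset-level exon-binding
    statistics. A deterministic synthetic-fixture generator (toy genome,
    annotation, peaks, planted motifs) supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
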