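Package: trflocus
Title: Annotation and Comparative Analysis of SpTransformer Immune Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locus-level characterization of the sea urchin SpTransformer (SpTrf)
    immune gene family from genomic contigs. Detects GA/GAT short-tandem-repeat
    islands, annotates the mosaic two-exon gene models from their conserved motif
    grammar (TATA box, initiator, splice signals, stop classes, polyadenylation
    signals), decomposes exon 2 into element patterns and types introns against
    reference sets, computes pairwise identity/coverage, gap-aware identity
    matrices, the percent-mismatch statistic, and Nei-Gojobori dN/dS with
    Jukes-Cantor correction, infers segmental-duplication blocks from
    seed-and-extend dot plots with STR-anchored edges, and builds neighbor-joining
    trees with bootstrap support. A seeded synthetic locus generator with full
    truth annotations makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
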