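Package: apatlas
Title: Alternative Polyadenylation Analysis from 3' End Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of alternative polyadenylation (APA) from
    3' end sequencing alignments. Identifies poly(A)-site-supporting (PASS)
    reads from soft-clipped oligo(T) evidence, clusters cleavage sites into
    a poly(A) site (PAS) atlas with abundance filters and gene/region
    annotation, quantifies PAS isoform and gene expression in reads per
    million (RPM), tests isoform switches between conditions with an exact
    pairwise test plus relative-expression-difference (RED) summaries and
    global trend ratios, scans PAS-flanking sequence with a position
    frequency matrix scored by information content, and performs k-mer and
    poly(A)-signal composition analyses. A synthetic-data module generates
    toy genomes, annotations, ground truth and SAM-format reads with the
    statistical structure the pipeline assumes, so every stage is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
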