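Package: ecdecon
Title: Reconstruction and Deconvolution of Circular Extrachromosomal DNA
    from Long-Read Structural Variants and Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs circular extrachromosomal DNA (ecDNA) structures
    from long-read whole-genome sequencing derivatives: structural-variant
    calls (Sniffles-style VCF) and an alignment coverage track. The genome
    is segmented at merged clean breakpoints, fragments and rearrangement
    junctions are encoded as a weighted undirected multigraph, simple
    circular paths are enumerated by a deterministic weighted depth-first
    search, and co-occurring circular elements with overlapping genomic
    footprints are deconvolved by a non-negative LASSO regression of
    fragment coverage on cycle membership. Includes a seven-class amplicon
    topology ranking, an ecDNA template simulator emitting matched
    idealized VCF/coverage/truth fixtures, and reconstruction evaluation
    metrics (normalized largest contig, breakpoint recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    GenomicAlignments,
    Rsamtools,
    glmnet,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
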