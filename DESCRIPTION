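Package: mirgrb
Title: Identification of MicroRNA Loci Under Long-Range Developmental Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Annotates and predicts microRNA loci that behave like target genes
    of genomic regulatory blocks (GRBs): self-transcribed miRNAs whose genomic
    neighbourhood is enriched in highly conserved non-coding elements (HCNEs)
    or p300-bound enhancers and whose putative promoters carry bivalent
    (H3K4me3 + H3K27me3) chromatin during development. Provides interval and
    annotation-track readers, miRNA classification and clustering, reciprocal
    best-hit ortholog calling by local alignment, search-window construction
    with protein-coding-gene truncation, 300 kb enhancer-density scans,
    matched random control sampling, bootstrapped Kolmogorov-Smirnov and exact
    contingency statistics, CpG-island features, and a synthetic annotation
    generator with planted targets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
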