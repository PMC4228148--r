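Package: polIIItx
Title: Strand-Specific Intergenic Differential Transcription Near Pol III
    Complex Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies altered intergenic RNA polymerase II
    transcription near RNA polymerase III complex binding sites (tRNA genes
    and extra-TFIIIC sites) from strand-specific RNA-seq. The genome is
    partitioned per strand into annotated gene space and 500-bp intergenic
    windows, uniquely mapped reads are counted by their 5' base, two-condition
    differential expression is assessed with median-of-ratios normalization
    and a conditional negative-binomial exact test with Benjamini-Hochberg
    correction, and differentially expressed intergenic regions are annotated
    for Pol III site proximity and classified as 5'-UTR extensions, 3'-UTR
    extensions, tDNA readthrough transcripts, or de-repressed intergenic
    regions. A synthetic-data module generates genomes, site registries, read
    sets and negative-binomial count matrices with planted events so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
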