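Package: episcreen
Title: Integrative Screen for Promoter-Hypermethylated, Epigenetically
    Silenced lncRNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrative epigenomic screen for long noncoding
    RNA genes silenced by promoter CpG-island hypermethylation in colorectal
    cancer: windowed chromatin-state annotation of transcription start sites
    from ChIP-seq peak sets, detection of H3K4me3 gain after DNA
    demethylation, promoter methylation summarization and filtering from
    reduced-representation bisulfite sequencing CpG counts, expression-based
    validation of candidate silenced genes, and downstream clinical
    statistics (elevated-methylation classification, methylation-expression
    correlation, Kaplan-Meier and optimal-cutoff log-rank survival
    analysis). A synthetic-data generator produces internally consistent
    annotation, peak, methylome, expression and clinical bundles with a
    planted truth set of silenced genes so that every stage of the screen is
    verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
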