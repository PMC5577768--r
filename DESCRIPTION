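Package: coregnet
Title: Seed-Centred Co-Expression Networks and Regulatory Motif Analysis
    for Insecticide-Resistance Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate transcriptional regulators of
    metabolic insecticide resistance from compendia of resistant-versus-
    susceptible expression contrasts. Builds seed-centred co-expression
    networks over transcript-by-experiment log2 fold-change matrices with a
    hard correlation threshold, quantifies recurrent differential expression
    across independent experiments with a binomial chance model, scans
    2-kb gene flanks for antioxidant response element (ARE) motifs by IUPAC
    consensus or position weight matrix, tests small transcript lists for
    annotation enrichment with the hypergeometric distribution, and provides
    the validation-arm statistics (delta-delta-Ct relative quantification
    with standard-curve efficiency QC, and arcsine-transformed ANOVA with
    Tukey post hoc tests for WHO-tube bioassay mortality). A synthetic-data
    module generates compendia, genomes, qPCR plates and bioassay records
    with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
biocViews: Transcriptomics, Network, MotifDiscovery, qPCR, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
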