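Package: ClusteredMutations
Title: Detection and Characterization of Clustered Somatic Mutations in Cancer Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects clustered somatic single-base substitutions and small
    indels in cancer genomes using sample-dependent intra-mutational distance
    (IMD) thresholds calibrated against context-preserving background
    simulations, and subclassifies clustered substitutions into doublet-base
    substitutions (DBS), multi-base substitutions (MBS), omikli, kataegis and
    other events. Provides structural-variant proximity modelling with
    Gaussian mixtures, assignment of kataegic events to focal amplifications
    including circular extrachromosomal DNA (ecDNA-associated kataegis,
    "kyklonas"), mutational spectrum matrices (SBS96, SBS288, ID83), greedy
    signature decomposition, APOBEC3 RTCA/YTCA enrichment scores, and a
    fully labelled synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
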