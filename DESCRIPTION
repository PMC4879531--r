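Package: gbsforge
Title: Design, Simulation, Calling and Validation for Restriction-Enzyme
    Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("gbsforge", "developers", email = "gbsforge@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and validating reduced-representation
    genotyping-by-sequencing (GBS) experiments. Performs in silico
    restriction digestion of a reference genome for enzyme selection and
    multiplex planning; simulates synthetic genomes, gene models, divergent
    founder lines, an F2 intercross pedigree and barcoded GBS reads;
    processes reads into a pooled 64-base tag catalog; discovers and calls
    biallelic SNPs with taxon/site coverage, minor-allele-frequency and
    duplicate-site filters; and computes the validation statistics used for
    GBS callsets (position and genotype concordance against a reference
    callset, Mendelian-error rates, heterozygosity summaries, inter-SNP
    distance and chromosome-class density tables, and two-point linkage
    grouping with Kosambi map distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
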