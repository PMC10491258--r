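Package: ptQTL
Title: Cell-Type-Specific Post-Transcriptional Quantitative Trait Locus Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and quantification of post-transcriptional molecular
    phenotypes -- A-to-I RNA-editing rates and 3'UTR poly(A) site usage (PAU) --
    and mapping of their cis genetic regulators. Editing QTLs (edQTLs) are
    mapped with a binomial generalized linear model on edited/total read
    counts; alternative-polyadenylation QTLs (apaQTLs) are mapped with an
    EMMAX-style linear mixed model using an identity-by-state kinship matrix
    with leave-one-chromosome-out support. Multiple testing is controlled
    hierarchically: per-phenotype adjustment by the eigenvalue-based effective
    number of independent cis variants, then Benjamini-Hochberg across
    phenotypes. Downstream statistics include pi1 replication sharing,
    MAF/distance-matched permutation enrichment of QTL variants in RNA
    secondary-structure categories, LD-thresholded conditional GWAS
    colocalization, and mediation model comparison. A synthetic-data module
    generates LD-structured genotypes, beta-binomial edit counts, multinomial
    isoform counts, relatedness, and GWAS summary statistics with known ground
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
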