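Package: smMIPseq
Title: Targeted Expression Quantification with Single-Molecule Molecular
    Inversion Probes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Design, simulation and analysis of cDNA single-molecule
    molecular inversion probe (smMIP) capture experiments. Provides probe
    panel design against spliced transcript models (including exon-exon
    junction probes and SNP probe pairs), alignment-free conversion of
    paired-end capture reads into sequencing-error-corrected unique-molecule
    counts, a Bayesian hierarchical negative-binomial model for normalized
    and differential expression with probe-bias correction, allele-specific
    expression by per-molecule majority vote, and a ground-truth read
    simulator covering capture-efficiency variation, PCR duplication and
    substitution sequencing errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    rjags,
    coda,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    rtracklayer,
    vcfR,
    Rsamtools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Sequencing, TargetedResequencing, Bayesian
RoxygenNote: 7.3.3
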