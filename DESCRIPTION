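Package: immuneLayers
Title: Layered Immune Gene Expression Analysis for Sponge Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a layered analysis of immune gene expression in bulk
    RNA-seq experiments on early-branching animals such as sponges.
    Transcripts are classified into pattern-recognition-receptor (PRR)
    families from Pfam domain-architecture rules; genes are partitioned into
    constitutive, individual-specific and unexpressed layers from
    presence/absence across samples; expression is normalized to
    TMM-scaled TPM; an LPS-induced response is called with a
    negative-binomial Wald test per timepoint; and differentially expressed
    genes are split into consistent and variable sets by replicate support
    within expression-pattern clusters. A synthetic-data generator with a
    planted truth table emulates the paired clone design (two treatments,
    two timepoints, replicated individuals) for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, Normalization,
    GeneExpression, ImmunoOncology
RoxygenNote: 7.3.3
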