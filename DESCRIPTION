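Package: MuSCplasticity
Title: Transcriptome and DNA-Methylome Plasticity of Muscle Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of transcriptome and DNA-methylome identity and
    plasticity of muscle stem cells from distinct anatomical locations
    (extraocular muscle and Tibialis anterior) before and after heterotopic
    transplantation. Provides element annotation (promoters, enhancers from
    H3K27ac peaks, enhancer-gene linking, Hox-cluster windows), per-element
    CpG methylation quantification with coverage filters, rolling Z-score
    differential methylation, consecutive-CpG DMR calling, graft-effect
    correction for expression and methylation, resistant/intermediate/
    responsive plasticity classification of location-specific genes, PCA and
    correlation clustering, and a fully seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
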