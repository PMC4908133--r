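Package: tagDGE
Title: Digital Gene Expression Tag Profiling of Pollen Developmental Stages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for NlaIII-anchored digital gene expression (DGE) tag
    profiling of bulk transcriptome libraries, built around the analysis of
    pollen germination and pollen tube growth. Provides virtual CATG+17-nt
    tag reference construction from transcript FASTA, raw tag library
    quality filtering with an exact accounting ledger, mismatch-tolerant
    tag-to-gene mapping with multi-gene exclusion, transcripts-per-million
    quantification, the Audic-Claverie exact test for differential
    expression with FDR control, hypergeometric GO/KEGG term enrichment,
    saturation and antisense analyses, hierarchical clustering with Eisen
    Cluster-compatible export, 2^-ddCt qRT-PCR concordance, and a fully
    parameterised synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, DifferentialExpression,
    Sequencing, Preprocessing
RoxygenNote: 7.3.3
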