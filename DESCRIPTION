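Package: somaticlone
Title: Somatic Mutation Inference and CpG-Context Indel Annotation for
    Clonally Amplified Whole Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers and characterizes somatic mutations from multi-clone
    whole-genome sequencing of clonally amplified single genomes (for example
    embryonic stem cell lines established from somatic cell nuclear transfer).
    Implements callable-region construction from depth tracks (depth-vs-peak
    bounds, MQ60/all-reads ratio, and base-quality masks), clone-unique variant
    filtering by variant allele frequency against sister clones, indel
    normalization and repeat-context classification, CpG-proximity and CpG
    gain/loss annotation, templated-duplication and deletion-junction
    microhomology detection, SBS96/ID83 mutation-signature matrices with
    non-negative least-squares refitting against reference catalogs, and
    interval/gene-model enrichment statistics. A synthetic-data generator with
    machine-readable truth tables emulates the clonal study design for testing
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    data.table,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: SomaticMutation, VariantAnnotation, Coverage, Software
RoxygenNote: 7.3.3
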