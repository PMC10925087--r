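Package: hapsomatic
Title: Tumour-Only Somatic Mutation Calling from Haplotype-Phased Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting somatic mutations in tumour samples without a
    matched normal, using single-molecule long reads. Includes closed-form
    Bayesian pileup classifiers for phased and unphased count data and a
    simulation framework to map the tumour-purity/depth/error regimes where
    tumour-only calling is feasible; a full calling pipeline with quality-aware
    pair-HMM read realignment, copy-number-aware genotyping of known SNP sites,
    read haplotagging from a phased VCF, per-haplotype somatic classification
    under a clonal/subclonal cancer-cell-fraction prior, and hard filters; plus
    tumour mutation burden estimation and 96-context mutation spectrum
    extraction. A synthetic fixture generator emits truth-annotated
    FASTA/BAM/VCF inputs so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
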