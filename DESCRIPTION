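Package: SVPopGen
Title: Consensus Structural-Variant Merging and Comparative SNP/SV Population Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative population genomics of single-nucleotide
    polymorphisms (SNPs) and structural variants (SVs) in invasion biology
    settings. Implements genotype-aware consensus merging of multi-caller SV
    calls (per-sample genotype-partitioned merging followed by a cross-sample
    merge), dataset-construction filters (missingness, minor allele frequency,
    linkage pruning, physical thinning, kinship screening), windowed SNP/SV
    density comparison via quasi-Poisson regression with subtelomeric
    enrichment summaries, per-population diversity statistics and folded site
    frequency spectra, principal component analysis of genotype dosages,
    differentiation-outlier scanning with an empirical pseudo-observed-data
    threshold, and a folded beta(1) balancing-selection scan whose SNP scores
    are propagated to SVs as trimmed-mean pseudo-scores. A fully seeded
    synthetic-data generator emulates a multi-population study design with
    imperfect SV callers so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3),
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, PopulationGenetics, VariantAnnotation,
    Software
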