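Package: cinprecursor
Title: Chromosomal Instability Metrics for Lung Adenocarcinoma Precursors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromosomal instability in early lung adenocarcinoma
    and its preinvasive precursors (AAH, AIS, MIA, ADC) from allele-specific
    copy-number segments, multi-caller somatic SNV call sets and sequencing
    reads. Implements arm-level major/minor allele copy-number profiling, a
    randomization test for whole-genome doubling with both Monte-Carlo and
    exact-enumeration null distributions, the weighted genome instability
    index (wGII), somatic copy-number alteration burden, aneuploid-chromosome
    counts and focal gene gain/loss calls, a multi-caller somatic SNV
    consensus filter with tumor mutational burden, and telomere-content
    estimation from reads using canonical and variant telomeric repeats.
    Ships seeded simulators for copy-number cohorts, multi-caller variant
    call sets and telomere read sets with known ground truth, so every stage
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stringi
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: CopyNumberVariation, SomaticMutation, Sequencing, Coverage,
    StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
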