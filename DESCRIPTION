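Package: adipomiR
Title: Small RNA-Seq miRNA Profiling of Visceral and Subcutaneous Adipose Depots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a small RNA sequencing analysis
    pipeline for comparing microRNA transcriptomes across adipose tissue
    depots. Provides read quality control and collapsing into unique tags,
    contaminant removal, two-tier precursor mapping with
    known/novel-star/conserved classification, expression matrix construction
    with tissue-presence categorization, a three-test consensus differential
    expression procedure (Audic-Claverie, Fisher exact, and Pearson chi-squared
    tests with Bonferroni correction), depot-specific enrichment calling
    across all visceral-versus-subcutaneous comparisons, and hierarchical
    clustering of expression profiles. Includes a synthetic-data generator
    that emulates six depot-structured libraries with planted effects and
    exported ground truth for end-to-end validation.
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
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'adipomiR-package.R'
    'annotate.R'
    'expression.R'
    'cluster.R'
    'diffexp.R'
    'refsim.R'
    'readqc.R'
    'pipeline.R'
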