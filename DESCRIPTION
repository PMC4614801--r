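Package: ModuleCrosstalk
Title: Functional Module Crosstalk Analysis in Disease Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking two disease contexts (for
    example chronic inflammation and cancer) through functional modules of
    a protein-protein interaction network. Differentially expressed genes
    are called per dataset with a SAM-style permutation statistic and
    integrated across datasets by direction-consistent majority support;
    integrated gene sets are mapped onto a high-confidence scored
    interactome; dense modules are detected with an MCODE-style
    vertex-weighting algorithm; crosstalk between module pairs from the
    two contexts is tested against a degree-preserving network
    randomization null; pivot transcription factors and microRNAs that
    significantly regulate both modules of a significant pair are
    identified with hypergeometric tests; and generic gene-set enrichment
    with Benjamini-Hochberg control is provided. A synthetic-data
    generator with planted modules, planted crosstalk, planted
    differential expression and planted pivot regulators supplies
    ground-truth test beds for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic-data.R'
    'differential-expression.R'
    'interactome.R'
    'mcode.R'
    'crosstalk.R'
    'regulators.R'
    'enrichment.R'
    'io.R'
    'pipeline.R'
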