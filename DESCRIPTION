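Package: leukoProfiler
Title: Inflammation Profiles: Cell-Type Enrichment from Bulk Expression Contrasts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers which leukocyte populations infiltrate a perturbed tissue
    from a case/control expression contrast and a panel of reference
    expression profiles. For each candidate population the package identifies
    signature transcripts (probes expressed far higher in the population than
    in the baseline tissue), scores how disproportionately those signatures
    rise in cases (the n1/n2 ratio), removes signatures shared with
    higher-scoring populations to de-correlate the tests, and assesses both
    scores with Hochberg-adjusted hypergeometric tests against the
    platform-wide background. Includes a moderated t-statistic for the
    differential-expression steps, attribution of top induced transcripts to
    significant populations, phenotype-correlation and predictor-screen
    utilities, and a spike-in mixture simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
biocViews: GeneExpression, DifferentialExpression, ImmuneOncology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
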