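Package: MetaboBiP
Title: Chemistry-Informed Bioactive Potential Scoring of Untargeted Metabolomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes metabolites from untargeted metabolomics panels by
    their predicted bioactivity against nuclear-receptor and stress-response
    screening endpoints. Curates chemical structures through a twelve-step
    standardization protocol, builds fixed-length structural feature vectors
    (5120-bit radius-2 circular fingerprints, MACCS keys, a 200-descriptor
    panel), trains class-weighted random-forest classifiers per endpoint with
    Bayesian hyperparameter optimization penalized by the Matthews correlation
    coefficient, gates models by cross-validated and test MCC, computes the
    concentration-weighted bioactive potential (BiP) and its log-sum (sBiP)
    per subject and metabolite, and tests the association of the scored
    metabolome with an inflammation outcome such as hs-CRP by multiple linear
    regression. Includes seeded generators for synthetic compound libraries
    with planted structure-activity rules and synthetic cohorts with planted
    metabolite-outcome effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineR,
    ChemmineOB,
    ranger,
    kernlab,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel (obabel and obtautomer on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metabolomics, Cheminformatics, Classification, Regression
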