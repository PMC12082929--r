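Package: csfnet
Title: Co-Expression Network Analysis of CSF Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for cerebrospinal-fluid (CSF)
    proteomic abundance matrices: median-polish-of-ratio (TAMPOR) batch
    harmonization, bootstrap covariate regression, differential protein
    abundance with Benjamini-Hochberg correction, signed weighted
    co-expression networks built on biweight midcorrelation and
    topological overlap, module-trait association and Fisher enrichment,
    permutation-based cross-cohort module preservation with synthetic
    eigenproteins, and discriminative biomarker panels. A synthetic-cohort
    generator with planted co-expression modules and group, age, sex and
    batch effects makes every stage verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
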