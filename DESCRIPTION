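Package: pgxreport
Title: Offline Pharmacogenomic Interpretation and Clinical Report Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates star-allele diplotypes, HLA allele presence calls and
    named-variant genotypes into inferred metabolizer phenotypes via curated
    diplotype-to-phenotype tables, adjusts CYP450 phenotypes for concomitant
    inhibitors and inducers (phenoconversion), resolves evidence-based
    prescribing recommendations through a CPIC > DPWG > FDA source-preference
    hierarchy, and renders a structured clinical report (JSON, Markdown or
    HTML). Ships a versioned knowledge-base bundle format (TSV + JSON
    manifest) with a loader, validator and self-contained fixture covering
    97 gene-drug pairs across 11 pharmacogenes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
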