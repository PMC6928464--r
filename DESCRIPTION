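Package: kintree
Title: Family Tree Database Construction and Kinship Coding from Household Rosters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpersonal family-tree databases from administrative
    household and health-insurance roster snapshots, in the style of the Korean
    National Health Information Database family tree. Implements a compositional
    three-character family-code algebra (parse, invert, compose, reduce,
    classify, degree of kinship), pedigree-graph construction by comparing and
    complementing two roster sources, enumeration of all kin pairs up to the
    fourth degree of kinship with canonical relationship codes, a synthetic
    multi-generation population generator with cohort-dependent record
    missingness and familially aggregated disease, and a family-history
    analysis layer (claims-based case definitions, family-history strata,
    direct age standardization by five-year age groups, matching-rate and
    kin-count reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
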