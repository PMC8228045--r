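Package: comorbidrules
Title: Comorbidity Association Rules for Hospital Discharge Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines association rules between comorbid diseases of patients
    hospitalized with mental and behavioral disorders. Maps ICD-10 diagnosis
    codes to intermediate classification blocks, applies study eligibility
    rules and descriptive statistics (prevalence tables, Pearson chi-square,
    Welch t from summary statistics), mines frequent itemsets with a
    level-wise Apriori implementation, selects and ranks rules by support,
    confidence, lift and the interest-support (IS, cosine) scale, and exports
    bipartite item/rule networks. Includes a synthetic discharge-record
    generator with planted pairwise block dependencies at a target lift and
    closed-form expected metrics for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
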