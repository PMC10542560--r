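Package: brainprior
Title: Prioritize Candidate Genes from Rodent RNA-Seq by Conservation and Human Brain Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for narrowing candidate gene lists from rodent RNA-seq
    studies by translational potential. Genes are categorized as High, Medium,
    or Low priority on evolutionary-conservation metrics (protein sequence
    similarity, dN/dS, developmental-expression conservation) and on human
    brain-expression metrics derived from a tissue-level TPM panel (brain
    specificity score, brain-region enrichment via two-way type III ANOVA with
    Tukey post hocs and compact letter displays, mean CNS expression, sex
    effects). Priority distributions can be compared across datasets with
    Monte-Carlo Fisher tests, and two-group RNA-seq designs can be planned with
    a negative-binomial Monte-Carlo power simulator. A synthetic-data module
    generates ortholog tables, developmental-conservation tables, and GTEx-like
    expression panels with planted effects so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
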