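Package: dmamr
Title: Mendelian Randomization of Arsenic Metabolism Efficiency on DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triangulating evidence that arsenic metabolism
    efficiency (urinary DMA%) causally influences DNA methylation at
    arsenic-associated CpG sites. Builds genetically predicted DMA% scores
    from SNP weights, fits per-CpG linear-regression association models under
    cohort-specific covariate sets, computes two-sample summary-statistic
    Mendelian randomization estimates (Wald ratio, inverse-variance weighted,
    and maximum likelihood), and evaluates directional consistency of the
    estimates against a prior EWAS sign vector with one-sided exact binomial
    tests. Includes a synthetic-cohort generator with the full causal
    structure (genotype -> DMA% -> internal dose -> methylation) so the whole
    pipeline is testable end to end without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
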