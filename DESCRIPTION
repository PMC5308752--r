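Package: oamlmut
Title: Targeted-Amplicon Mutation Analysis of Ocular Adnexal MALT Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of targeted amplicon sequencing of
    ocular adnexal marginal zone lymphoma (OAML) cohorts: a reproducible
    variant-filter cascade for FFPE-derived call tables (quality, coverage,
    allele-frequency bands, primer proximity, amplicon overlap concordance,
    known-SNP and blacklist exclusion), consequence annotation with a
    five-tool damaging consensus and protein-domain mapping, cohort mutation
    landscape statistics with VAF-based clonality calls and Fisher
    mutual-exclusivity screening, Kaplan-Meier disease-free-survival
    stratification by mutation status, and a synthetic FFPE-amplicon cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
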