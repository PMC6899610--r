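Package: hemotyper
Title: Hemoglobinopathy Carrier Screening, Clinical Genotyping, and At-Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for molecular screening and clinical genotyping of
    hemoglobinopathies. Provides a curated variant knowledge base (HGVS/rsID/coordinate
    lookup, ACMG five-tier classes, candidate-region validation), a hematologic
    carrier-inference decision tree over red-cell indices and the Hb pattern, a
    combinatory genotype rule engine that integrates alpha-globin copy number,
    beta-globin allele classes, and HbF modifier loci (KLF1, XmnI/HBG2, BCL11A, HMIP)
    into an overall diagnosis with modifier-adjusted beta-thalassemia severity, a
    Mendelian at-risk assessment for couples, a carrier versus non-carrier HbF
    quantitative-trait association scan with Bonferroni correction, and a synthetic
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
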