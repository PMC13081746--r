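Package: triomethyl
Title: Direct and Indirect Genetic Effects of Birthweight Predisposition
    on Neonatal DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based decomposition of direct (fetal) and indirect
    (maternal/paternal) genetic effects of birthweight predisposition on
    cord-blood DNA methylation. Provides polygenic-score and
    methylation-profile-score construction with allele harmonization,
    genetic principal-component residualization, beta/M-value conversion
    and nearest-neighbour imputation; a duo/trio/GWAS-adjusted linear
    model battery with sex interactions; inverse-variance fixed-effect
    meta-analysis across array subcohorts with Benjamini-Hochberg FDR
    control; multiple-mediator path models with FAMD-style imputation of
    mixed-type prenatal mediators, bootstrap intervals and proportion
    mediated; and a trio-cohort simulator (Hardy-Weinberg genotypes,
    Mendelian transmission, reference-cohort GWAS weights, a two-array
    neonatal methylome) so the whole pipeline is testable without
    restricted cohort data.
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
    metafor,
    vcfR,
    withr
Config/testthat/edition: 3
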