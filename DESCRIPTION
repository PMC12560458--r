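Package: gscreen
Title: Drug Sensitivity Scoring and Multi-Omic Resistance Profiling for
    Patient-Derived Tumor Culture Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo drug screens of patient-derived
    glioblastoma stem cell (GSC) cultures. Fits four-parameter logistic
    dose-response curves to plate-normalized viability data, summarizes each
    curve as a Drug Sensitivity Score (DSS, the normalized area of drug
    activity above a 10 percent inhibition floor), classifies cultures into
    drug-resistant and drug-sensitive groups by Ward.D2 hierarchical
    clustering of per-drug centered DSS profiles with multiscale-bootstrap
    cluster stability (AU/BP values), and contrasts the groups downstream:
    rank-normalized stemness set scores, single-sample gene set enrichment
    (ssGSEA) proneural/mesenchymal subtype calls, hypergeometric
    over-representation analysis, CpG-island methylation aggregation from
    bedMethyl files, MGMT promoter methylation classification, differential
    island methylation, and inverse methylation-expression linkage. A
    seeded multi-modal synthetic-cohort generator with planted group
    structure makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
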