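Package: ppbcsig
Title: Expression Signatures, TCR Repertoire Diversity and Survival
    Stratification for Postpartum Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for contrasting postpartum (PPBC) against nulliparous
    (NPBC) ER-positive young women's breast cancer from bulk RNA-seq counts:
    CPM filtering and two-group differential expression with
    Benjamini-Hochberg FDR; weighted Kolmogorov-Smirnov gene set enrichment
    with permutation NES and single-sample gene-set scores; rank-based
    single-sample transcription-factor regulon activities and a composite
    prognostic signature (immune exhaustion + E2F1 - TP53 - ESR1); PAM50
    nearest-centroid subtyping and a pseudo 21-gene recurrence score; T-cell
    receptor repertoire diversity (Shannon entropy, clonality, Gini, clonal
    space occupancy); Kaplan-Meier/log-rank median-split survival analysis;
    and multi-study cohort assembly with probe collapsing and per-study
    standardization. Includes a seeded synthetic-data generator emulating the
    cohort structure so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
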