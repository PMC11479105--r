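Package: fcdblink
Title: Cross-Country Food Composition Database Harmonization and Concordance
Version: 0.1.0
Authors@R:
    person("fcdblink", "developers", email = "fcdblink@example.org",
           role = c("aut", "cre"))
Description: Tools for linking dish-level ingredient metadata in the
    Nutrition5k ragged-wide CSV dialect to a national food composition
    database (FCDB), harmonizing component definitions between two FCDBs
    (available carbohydrates, vitamin A and tocopherol equivalents,
    short-chain saturated fatty acids), applying expert curation tables
    (plate-only removal, missing-name recovery, mass corrections, trace and
    missing-value imputation), aggregating per-100 g compositions to
    dish-level nutrient totals, and comparing totals computed under two
    FCDBs with a paired-agreement battery (Pearson correlation, quintile
    cross-classification with unweighted Cohen's kappa, Bland-Altman limits
    of agreement, difference summaries, Kolmogorov-Smirnov and Wilcoxon
    signed-rank tests) and a robust MM-estimator regression of difference
    determinants. Includes a seeded synthetic-data generator that emulates
    paired FCDBs differing by the fiber-in-carbohydrate definitional offset,
    so the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
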