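Package: aghdscreen
Title: Rule-Based Likelihood Stratification of Adult Growth Hormone
    Deficiency in Healthcare Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A computable phenotype for adult growth hormone deficiency
    (AGHD) on longitudinal administrative claims. Implements a rule-based
    engine that assigns every eligible adult a high, moderate, or low
    likelihood tier from diagnosis (ICD-9-CM/ICD-10-CM), procedure (CPT),
    and pharmacy (ATC) claims, driven by editable, versioned code lists;
    cohort characterization statistics (tier and reason proportions,
    age/sex tables, last-year comorbidity incidence, standardized
    differences between tiers); a seeded synthetic-claims generator with
    planted archetypes for every algorithm branch; and a command-line
    interface for simulate/classify/summarize workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
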