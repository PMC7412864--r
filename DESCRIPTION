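Package: pbaescreen
Title: Chemometric Screening of Poly-Beta-Amino-Ester Drug Conjugate Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the chemometric analysis of poly-beta-amino-ester
    (PBAE) drug-conjugate libraries screened as cartilage drug delivery
    systems. Provides a polymer descriptor-table data model with validation
    and standardization, hierarchical clustering of polymers on Manhattan
    distances with complete linkage, a from-scratch NIPALS partial least
    squares (PLS) regression linking physicochemical descriptors to cartilage
    drug-uptake ratios with scree-based component selection, variance
    bookkeeping, loading maps and descriptor-response correlation profiles,
    break-through-time (time-lag) estimation of polymer diffusion
    coefficients through cartilage, uptake-ratio and glycosaminoglycan (GAG)
    efficacy statistics (one-tailed Welch tests, one-way ANOVA with Tukey
    post hoc), and seeded synthetic-data generators emulating every measured
    input so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    ape,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
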