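Package: admixscan
Title: Admixture Mapping of Quantitative Traits in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Local-ancestry association (admixture) mapping for admixed
    cohorts such as Hispanic/Latino populations with European, African and
    Amerindian ancestry components. Provides a synthetic-cohort simulator
    with known local ancestry, genotypes, household/block clustering and
    blood-pressure phenotypes; phenotype preparation with medication
    adjustment, exclusion rules and winsorization; linear mixed models with
    kinship, household and block random effects fitted by REML; one- and
    two-degree-of-freedom Wald scans of local ancestry interval counts;
    significant-region detection and effective-number-of-traits estimation;
    EM estimation of ancestry-specific effect-allele frequencies from
    unphased genotypes; candidate-variant fine-mapping with correlation
    pruning and conditional scans; analytic power comparison of admixture
    versus association testing; and one-sided replication tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
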