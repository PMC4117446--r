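Package: onsetGWAS
Title: Age-at-Onset Informed Genome-Wide Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Covariate-informed association testing for case-control
    genome-wide association studies in which disease prevalence varies
    strongly with age, such as ischaemic stroke and its subtypes.
    Implements the age-structured liability-threshold model: age-specific
    prevalence is converted into liability thresholds, each sample is
    assigned the posterior mean liability given affection status and
    age-at-onset (cases) or age at exam (controls), and SNP dosages are
    tested against these liabilities with an N times squared-correlation
    score test. Includes per-study quality-control filters for imputed
    dosages, sample-size weighted Stouffer meta-analysis with genomic
    control, Cochran's Q heterogeneity assessment, case-coverage and
    heterogeneity filters, fixed-effects and Han-Eskin random-effects
    replication meta-analysis, Fisher's method for combining discovery
    and replication evidence, greedy LD clumping, and a within-study
    age-permutation framework that quantifies genome-wide age-at-onset
    effects via a summed-Z statistic. A synthetic-cohort generator
    simulates multi-centre case-control studies under the same
    age-structured liability model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
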