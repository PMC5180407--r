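Package: oncoreport
Title: Tumor-Normal Somatic Analysis and Tiered Clinical Reporting for
    Pediatric Oncology Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream computation for paired tumor-normal clinical
    sequencing of pediatric cancer and high-risk hematologic disease:
    somatic variant identification by subtraction of normal-tissue calls
    under allelic-fraction output thresholds, three-layer germline
    filtering (reference range, reportable range, population frequency),
    variant categorization and mutational-load statistics, exome CNV
    quality gating with copy-neutral loss-of-heterozygosity detection
    from B-allele fractions, housekeeping-normalized expression-outlier
    calling against a panel of normal transcriptomes, fusion annotation
    against known-fusion catalogs, evidence-tiered actionability
    classification, and structured molecular tumor board report
    rendering.  Includes a seeded synthetic-data generator with planted
    truth for end-to-end validation, and cohort analytics over bundled
    curated finding tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
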