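Package: gutapns
Title: Gut Microbiome Contributions to Adverse Post-Traumatic Neuropsychiatric Sequelae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking gut microbiome taxonomic and functional
    profiles to adverse post-traumatic neuropsychiatric sequelae (APNS) in a
    longitudinal emergency-department cohort. Reads MetaPhlAn-style species
    relative-abundance tables and HUMAnN-style stratified pathway tables;
    scores PTSD (PCL-5), depression (PROMIS 8b t-score) and somatic-symptom
    (Rivermead) outcomes; screens species with arcsine-square-root linear
    mixed models under Benjamini-Hochberg false-discovery control and
    partitions outcome variance by sequential ANOVA; fits a mixed-effect
    random forest (regression forest plus BLUP random intercepts, alternated
    by EM) with a longitudinal time split and permutation variable
    importance; tabulates per-taxon pathway contributions stratified by
    diagnosis group; and computes Spearman-correlation power. Includes a
    synthetic-cohort generator with planted species effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
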