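Package: cohortpheno
Title: Phenotype Ascertainment from Harmonized Biobank Health Records
Version: 0.1.0
Authors@R:
    person("Cohort", "Phenotyping Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to generate binary health-outcome phenotypes in large
    population cohorts of the UK Biobank kind. Machine-actionable phenotype
    definition tables (ICD-9/ICD-10/OPCS-4/READ2/CTV3 codelists with
    hierarchical parent-code expansion, self-report field specifications and
    touchscreen conditions) are parsed and validated; the main per-participant
    dataset, hospital inpatient episodes, primary-care events and
    prescriptions, and the death register are harmonized into a single
    clinical-episode schema; case/control status is ascertained per
    participant with prevalent/incident/time-to-event semantics, composite
    inclusion/exclusion logic and censoring-aware follow-up derivation. A
    fully synthetic cohort generator emulates every input format with known
    ground truth so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    xml2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
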