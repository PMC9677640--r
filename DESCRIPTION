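Package: coughcohort
Title: Cohort Identification and Drug-Utilisation Analysis for Chronic Cough in Monthly-Granularity Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computable phenotype for chronic cough in
    administrative claims databases where diagnoses are recorded at month
    granularity and prescriptions at day granularity. Identifies two mutually
    exclusive populations (an explicit chronic-cough diagnostic code, or a
    temporal pattern of repeated cough codes spanning more than eight weeks),
    derives index months, applies eligibility screening (age, ACE-inhibitor
    use, organic respiratory disease and cancer exclusions, enrolment
    continuity), and extracts longitudinal summaries: cough-code persistence,
    cough-related disease prevalence in fixed windows, and medication-class
    utilisation in four-week windows around post-index time points, split by
    central-antitussive co-prescription. Ships a synthetic claims generator
    with planted ground-truth cohort members for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
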