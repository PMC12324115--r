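Package: pdtraj
Title: Day-Resolved Care-Trajectory Reconstruction for Peritoneal Dialysis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs kidney-replacement-therapy care trajectories from
    day-level dialysis event streams, as recorded in exhaustive claims
    databases. Collapses per-day hemodialysis sessions, peritoneal-dialysis
    coverage days, transplant and death events into maximal modality episodes,
    classifies six states (peritoneal dialysis, hemodialysis, mixed dialysis,
    hybrid dialysis, transplantation, death) with rule-based definitions of
    the unstable mixed regime and the stable hybrid regime, and summarises
    trajectories as transition tables, pattern-level duration tables,
    modality-count distributions and step-indexed Sankey graphs. Ships a
    synthetic-cohort simulator driven by trajectory archetypes so that every
    stage can be exercised and validated without access to restricted
    registry or claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
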