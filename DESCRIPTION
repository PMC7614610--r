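Package: onlinetrial
Title: Online Error Rate Control for Platform Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying online multiple-testing
    procedures in platform trials, where experimental arms enter over time
    and are compared against shared concurrent controls. Provides a
    platform-trial data generator (staggered arm entry, normally
    distributed outcomes, concurrent-control z-statistics), fully online
    testing procedures (LOND, LORD, SAFFRON, ADDIS, ADDIS-spending,
    Bonferroni), online batched procedures (BatchBH, BatchPRDS, BatchStBH
    and naive per-batch comparators), offline comparators (BH, Storey-BH,
    Holm), a replicated-simulation engine estimating familywise error
    rate, false discovery rate, disjunctive power and sensitivity, and a
    deterministic re-analysis of the published STAMPEDE p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
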