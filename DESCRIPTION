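Package: searchshare
Title: Share-of-Search Analysis of Geographic Disparities in Symptom Searching
Version: 0.1.0
Authors@R:
    person("Search Share", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing anonymized, inconsistently scaled county-level
    symptom search-weight panels. Computes the share-of-search statistic (each
    symptom's weight as a percentage of all symptom searching in the same
    county and biweekly period), which is invariant to unknown per-region
    scale factors; builds mental-health symptom sets from dual-coder labels
    (Cohen kappa), co-search affiliation expansion and exclusion rules; and
    runs stratified two-group and pre/post contrasts (health-professional
    shortage vs nonshortage areas, rural/micropolitan/metro tiers) with
    Benjamini-Hochberg false-discovery-rate Q values. Includes a synthetic
    panel generator with planted multiplicative group effects, per-region
    scale confounding, differential-privacy-style noise and suppression, so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
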