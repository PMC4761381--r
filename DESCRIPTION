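Package: apmstools
Title: Identification of Bona Fide Interaction Partners from Quantitative AP-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quantitative affinity-purification mass-spectrometry
    (AP-MS) experiments, such as SILAC pull-downs of a tagged bait protein. Provides
    template-driven parsing of arbitrary column-separated search-engine exports into a
    uniform dataset, per-protein enrichment statistics (log2 ratios and one-sided paired
    t-tests with an insufficiency rule), contaminant flagging against bead-proteome and
    frequency-library marker lists, merging of PSI-MI TAB interaction-database dumps into
    a nonredundant score-annotated network, bait-centric focused/specialized/truncated
    network construction with score thresholds and static layouts, volcano-plot
    significance-region selection, condition-dependent (differential) binding calls,
    known-partner annotation, and a seeded synthetic AP-MS generator plus packaged
    example data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
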