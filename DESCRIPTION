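Package: ginet
Title: In Silico Genetic Interaction and Essentiality Network Mapping from
    Cancer Dependency Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps genetic networks of a query gene from DepMap-style CRISPR
    dependency screens. Provides co-essentiality mapping with
    permutation-adjusted Pearson correlations and knee-point thresholds on the
    ranked coefficient curve, differential-lethality genetic-interaction
    screening (Mann-Whitney rank-sum tests with a permutation-calibrated
    adjustment and an interaction score combining significance with the log2
    fold change of group median lethality probabilities), candidate
    prioritisation by statistical tier and drug-tractability group, enriched
    gene-set term clustering (hypergeometric over-representation, Jaccard
    similarity, gap-statistic cluster selection), and cohort marker scoring
    (tumour mutation burden, microsatellite-instability calls, cytolytic and
    immune signature scores). A seeded synthetic-data module generates
    DepMap-like dependency panels and expression cohorts with planted ground
    truth so the whole pipeline can be exercised and benchmarked without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
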