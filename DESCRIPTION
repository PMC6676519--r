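Package: sigbench
Title: Benchmarking Directional Gene Signatures Against Random Gene-Set Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores directional gene signatures on expression cohorts with a
    per-sample rank statistic, and benchmarks them against empirical null
    distributions of randomly sampled gene-sets under within-cohort repeated
    split validation and cross-cohort external validation. Supports stratified
    sampling pools (whole array, below-detection background probes,
    exclusion-filtered), age- and sex-matched case-control designs, empirical
    and Mann-Whitney significance with Benjamini-Hochberg correction, and a
    synthetic multi-cohort expression generator with planted signal,
    batch-class confounding and non-expressed background probes for end-to-end
    testing of the benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
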