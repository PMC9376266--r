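Package: sanet
Title: Segmented Attractor Networks for Lifelong Associative Memory
Version: 0.1.0
Authors@R:
    person("Alex", "Mercer", email = "amercer@example.org", role = c("aut", "cre"))
Description: Simulates the segmented attractor network (SAN), a recurrent
    associative memory that stores categorical memories as binary Hebbian
    weights between feature neurons of disjoint sets and recalls them by
    pattern completion from partial input. Provides a categorical dataset
    model with CSV input/output, a synthetic dataset generator with exact
    control over per-set uniqueness and planted common features, the three
    cognitive learning behaviors (prediction, erase/consolidation, and
    forgetting by synaptic decay), the lifelong-learning simulation loop,
    and the evaluation metrics: uniqueness-stratified hit rate, unique
    memory ratio, and per-memory recall occurrences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
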