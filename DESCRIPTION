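Package: synthgraph
Title: Learning Synthea Disease-Module Graphs from OMOP Patient Event Histories
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns weighted temporal-rule graphs from OMOP-formatted patient
    event histories and maps them into valid Synthea generic disease modules.
    Patient diagnoses and procedures are extracted into per-patient discrete
    event sequences with start/stop sentinels; directed rules are learned with
    a first-order Markov chain, sequential association rule mining (sequential
    support and confidence over a sequence database), and a from-scratch
    DYNOTEARS estimator of a structural vector autoregressive model under the
    smooth trace-exponential acyclicity constraint. Learned graphs are emitted
    as Synthea module JSON (Encounter states, distributed transitions) that can
    be sampled to produce synthetic event histories, and are compared with
    directed-graph complexity measures (density, directed clustering, strongly
    connected components, flow hierarchy) and pairwise edge overlap. A
    synthetic cohort generator with known ground-truth transition graphs and
    stable SVAR processes supports end-to-end recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
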