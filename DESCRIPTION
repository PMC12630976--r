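Package: metasimbn
Title: Meta-Simulation Benchmarking of Machine-Learning Method Selection
    with Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-simulation studies of machine-learning method
    selection under limited data. A known discrete Bayesian network acts as
    the data-generating process; candidate classifiers are benchmarked
    directly on small samples (the limited-real strategy) and on synthetic
    data drawn from data-generating processes inferred by structure
    learners, and both are compared with the asymptotic ground-truth
    performance. Includes a BIF reader/writer, forward (ancestral)
    sampling, maximum-likelihood CPT fitting, score-based (hill-climbing,
    tabu), constraint-based (PC-stable) and hybrid (MMHC) structure
    learning implemented from first principles, structural Hamming
    distance and Jensen-Shannon fidelity diagnostics, and reporting of
    bias, centred relative performance, and rank consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    nnet,
    ranger,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
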