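Package: seqbo
Title: Bayesian Optimization of Combinatorial Protein Sequence Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop, model-guided protein engineering over
    combinatorial Golden Gate assembly libraries. Represents a library as a
    DNA assembly graph whose Start-to-Stop paths enumerate all assemblable
    gene variants, models the sequence-function landscape with a multi-output
    Gaussian process (a Laplace-approximation classifier for activity and an
    exact regressor for thermostability sharing a linear Hamming kernel),
    ranks candidates with upper-confidence-bound acquisition rules including
    batch selection by fantasy updates, and runs autonomous design-test-learn
    campaigns against either a synthetic landscape oracle or a file-exchange
    executor. Includes assay reduction (progress-curve rates, shifted-sigmoid
    T50 fits, Michaelis-Menten kinetics, quality-control gates) and a
    simulation benchmark harness comparing acquisition strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
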