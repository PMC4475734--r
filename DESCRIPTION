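Package: stspdyn
Title: Short-Term Synaptic Plasticity Dynamics of Striatal GABAergic Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analyses short-term synaptic plasticity (STSP) of
    GABAergic synapses onto striatal projection neurons. Implements a
    two-variable presynaptic release model (readily releasable pool occupancy
    and release probability driven by pulse trains), descriptive fitting of
    normalized IPSC trains by a product of exponentials, sigmoid fitting of
    intensity-amplitude relationships with a recruitment index, variance-mean
    quantal analysis yielding quantal size, release-site count and weighted
    release probability, classification of train dynamics into depressing,
    facilitating and biphasic classes, and a seeded binomial generator of
    synthetic quantal sweep data for end-to-end pipeline validation in
    control and dopamine-depleted regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
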