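Package: padicwc
Title: Hierarchical p-Adic Wilson-Cowan Neural Field Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates excitatory-inhibitory Wilson-Cowan population
    dynamics on the hierarchical (ultrametric) domain given by the p-adic
    integers truncated at level l, i.e. on the p^l leaves of a rooted
    p-ary tree.  Provides finite-level p-adic arithmetic (norms, balls,
    Haar quadrature, the Monna map), radial exponential coupling kernels,
    two-term logistic sigmoids, the stimulus protocols used in classical
    binocular-hysteresis and pulse experiments, fixed-step integration of
    the discretized integro-differential system via cyclic group
    convolution, and an algorithm that approximates empirical cortical
    connection matrices by locally translation-invariant p-adic kernels
    which can be plugged into the dynamics as general integral operators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
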