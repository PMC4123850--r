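Package: nestadapt
Title: Adaptive Management of Recreational Restrictions at Raptor Nesting Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Belief-state Markov decision tools for adaptive management of
    recreational restrictions around golden eagle nesting territories. Builds
    exact joint signal/next-state probability kernels for N exchangeable sites
    from a single-site occupancy and fledging-success model (category-count
    multinomial convolution), updates Bayesian weights over competing
    disturbance-effect models from occupancy transitions and fledging-success
    signals, solves active and passive management strategies by value iteration
    on a discretized three-model belief simplex, compares information
    structures in the Blackwell (garbling) order, and simulates learning
    curves under alternative monitoring signals.
License: MIT
Encoding: UTF-8
Imports:
    boot,
    pracma,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
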