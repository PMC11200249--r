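Package: softmsm
Title: Ensembles of Neural Soft Markov State Models with Optimal-Transport State Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns soft Markov state models of biomolecular conformational
    dynamics from molecular-dynamics trajectory features with ensembles of
    neural state-assignment networks trained on a variational (VAMP-E) score.
    States are aligned within a system by constrained k-means on per-state
    average inter-residue distance matrices, and across systems by
    Wasserstein-1 optimal transport plus Hungarian matching with a
    cost threshold. Provides constrained (reversible, non-negative) Koopman
    estimation with equilibrium distributions, mean first-passage times,
    implied timescales and Chapman-Kolmogorov validation; gradient-based
    (saliency) characterization of learned states; tICA projections with
    kernel-density free-energy surfaces; a ground-truth hidden-Markov
    synthetic data generator; and a configurable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
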