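Package: touchnet
Title: Microcircuit Connectivity Prediction by Touch Detection
Version: 0.1.0
Authors@R:
    person("touchnet", "authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for predicting synaptic connectivity in large-scale
    microcircuit models. Places neuron somas inside mesh-bounded volumes
    under a minimum-separation constraint, rasterizes SWC neuron
    morphologies into voxels to detect putative synapses and gap junctions
    at axon-dendrite appositions, reduces the putative set with a
    multi-stage stochastic pruning rule (distance-dependent, f1, soft-max,
    mu2 sigmoid, a3 decimation) with an exact analytic expectation oracle,
    generates correlated Poisson external input via a thinned mother
    process, and repairs and augments SWC reconstructions (z-jump repair,
    cut-neurite grafting, shrinkage correction, length-preserving
    randomisation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
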