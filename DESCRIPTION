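Package: hdrpop
Title: Hypothesis-Guided Dimensionality Reduction for Neural Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing population dynamics across simultaneously
    analyzed neural populations. Implements hypothesis-guided dimensionality
    reduction (HDR), which finds a row-orthonormal projection partitioned into
    condition-invariant and dynamical dimensions by minimizing a tripartite
    cost over the Stiefel manifold; least-squares fitting of unconstrained,
    symmetric, skew-symmetric and best-fit purely rotational linear dynamics
    with rotational-frequency extraction; condition-invariance and
    context-variance statistics; jPCA- and PCA-based baseline dynamics
    assessments; condition, dimension and neuron bootstrap significance
    procedures; standard population analyses (population vector, population
    PSTH, frequency spectra); and a synthetic population generator with known
    latent ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
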