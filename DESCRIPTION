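Package: hyperlink
Title: Inter-Brain Connectivity Analysis for Hyperscanning Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-participant ("hyperscanning") EEG analysis: epoch
    containers with dyad merge/split semantics, cross-participant artifact
    rejection, Welch power spectra and analytic-signal decomposition into
    integer-Hz frequency bins, ten inter/intra-brain connectivity metrics
    (phase, envelope, coherence and directed families) assembled into joint
    two-participant block matrices, non-parametric permutation statistics
    with space-frequency cluster correction, topographic inter-brain link
    visualization, and a synthetic coupled-dyad generator with known
    ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'mvar.R'
    'connectivity-metrics.R'
    'connectivity-matrix.R'
    'epochs-io.R'
    'hyperlink-package.R'
    'preprocessing.R'
    'spectral.R'
    'stats-adjacency.R'
    'stats-permutation.R'
    'synthgen.R'
    'viz.R'
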