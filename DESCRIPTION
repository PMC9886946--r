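Package: treebp
Title: Tree-Structured Networks with Single-Route Pruned Backpropagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and trains shallow tree-structured feedforward networks
    (grouped convolution, max-pooling, a per-branch tree-sampling layer and
    one fully connected readout) in which every weight reaches every output
    unit through exactly one route. Provides a reference chain-rule
    backpropagation engine and an equivalent single-route pruned engine that
    visits only active routes, an exact route-enumeration analyzer for
    layered connectivity DAGs together with the closed-form LeNet-5 route
    arithmetic, gradient-sparsity profiling (structural zero-gradient
    fractions, magnitude-threshold pruning, active-update accounting),
    a synthetic labelled-image task generator, readers for the MNIST IDX and
    CIFAR-10 binary formats, and a command-line interface for training,
    describing architectures, counting routes and profiling sparsity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
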