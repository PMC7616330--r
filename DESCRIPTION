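Package: mdfr
Title: A Serializable Computational-Graph Model Description Format
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building, validating, exchanging and executing
    computational-graph model descriptions that span biophysical neuron
    models, cognitive accumulator models and tensor-based machine-learning
    networks. Models are graphs of nodes (input ports, parameters,
    functions, output ports) joined by edges, serialized losslessly to
    JSON, YAML or a binary encoding. A condition-based scheduler supports
    arbitrary control flow including multiple timescales and cyclic
    graphs; a reference execution engine evaluates nodes, propagates
    values along edges and integrates stateful parameters through
    simulated time (forward Euler). A function ontology provides a core
    tensor-operator set plus FitzHugh-Nagumo and drift-diffusion
    integrators, and bridges export model structure to Graphviz DOT and
    to a flat tensor-graph dialect.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
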