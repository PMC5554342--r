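Package: conceptboard
Title: Neural Blackboard Sentence Binding and Entropy-Driven Hierarchical
    Sequence Chunking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two complementary cognitive architectures and a bridge
    between them. The neural blackboard architecture represents sentence
    structure by temporary bindings between in-situ concept assemblies,
    realized as gating circuits and bistable working-memory populations
    simulated with Wilson-Cowan rate dynamics. The information-dynamics
    sequence learner builds a layered memory over symbol streams by
    boundary-entropy chunking with first-order Markov prediction per layer,
    grounded in geometric conceptual spaces partitioned by gap- and
    expectation-modulated Voronoi tessellations. A compiler maps learned
    chunk hierarchies onto blackboard binding structures, and fixture and
    synthetic-corpus generators make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
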