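Package: motifemerge
Title: Emergence of Network Motifs in Multi-Layer Perceptrons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how network motifs (recurring local connection
    patterns) emerge in small multi-layer perceptrons during learning.
    Generates two synthetic classification environments with contrasting
    covariance structure (a hierarchical binary-tree diffusion model and an
    independent-clusters model), trains fully connected ReLU/softmax networks
    from scratch with mini-batch gradient descent and Nesterov momentum under
    Normal, Orthogonal and Glorot weight initializations, prunes negligible
    weights by a Gaussian density cutoff, and quantifies 3-5-node motif
    significance via exact ESU subgraph enumeration, exhaustive canonical
    labeling and Z-scores against degree-preserving switch-randomized null
    ensembles.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
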