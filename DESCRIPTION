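Package: cider
Title: Causal Inference of miRNA Targets with Regulatory Knowledge
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based causal discovery for miRNA target prediction
    from matched miRNA and mRNA expression profiles. Experimentally
    validated regulatory interactions (TF-to-miRNA and miRNA-to-mRNA) are
    encoded as constant edges that are never removed or re-oriented during
    PC-style structure learning, and miRNA-mRNA causal effects are ranked
    by intervention-calculus lower bounds (minimum absolute effect over
    the admissible orientations of the learned partially directed graph).
    Includes a linear structural-equation simulator for benchmark
    networks, Pearson / Lasso / Z-score baselines, and F-score evaluation
    utilities for knowledge-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
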