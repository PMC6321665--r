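Package: lvqfold
Title: Interpretable Matrix Relevance Learning for Early Folding Residue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prototype-based classification of early versus late folding
    residues with Generalized Matrix Learning Vector Quantization (GMLVQ).
    Provides the full structural feature pipeline: residue interaction
    graphs built from covalent, hydrogen-bond, hydrophobic and C-alpha
    distance contacts; graph centrality descriptors; secondary-structure
    derived features; Shrake-Rupley relative accessible surface area;
    window averaging and z-score standardization. The classifier optimizes
    confusion-matrix based cost functions (accuracy, weighted accuracy,
    F-beta, precision-recall combinations) by stochastic gradient ascent
    and exposes the learned relevance mapping as a Classification
    Correlation Matrix for model interpretation. Includes stratified
    cross-validation, ROC analysis, a synthetic data generator and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    foreign,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
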