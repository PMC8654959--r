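Package: ACPcnn
Title: Multi-Headed Convolutional Classification of Anticancer Peptides
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies anticancer peptides (ACPs) from primary sequence with a
    compact multi-headed convolutional neural network. Peptides are truncated to
    their k N-terminal residues, post-padded, and encoded into three fixed-shape
    numeric matrices: a binary one-hot profile, a 31-bit physicochemical
    group-membership profile, and rows of the BLOSUM62 substitution matrix. Each
    active representation feeds its own stack of two 1-D convolutional layers;
    the flattened branch outputs are concatenated and recombined by dense layers
    ending in a two-way softmax. Training uses dropout, an L2 penalty, the Adam
    optimizer and early stopping, all seeded for exact reproducibility. The
    package also provides stratified k-fold cross-validation, independent-test
    evaluation, the standard confusion-matrix metric suite (accuracy,
    sensitivity, specificity, precision, Matthews correlation coefficient),
    ROC/AUC, a sweep over the seven representation combinations, a synthetic
    motif-implant peptide generator for fully offline experiments, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
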