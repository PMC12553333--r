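Package: protbench
Title: Neural Protein Sequence Learning and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained framework for protein sequence learning: five
    task types (single-protein regression and classification, protein-pair
    regression and classification, and residue-level classification), token
    and molecular-graph featurization of amino-acid sequences, a model zoo of
    sequence architectures (CNN, CNN-GRU, transformer), graph neural networks
    over peptide molecular graphs (GCN, GAT, MPNN, NeuralFP, AttentiveFP,
    PAGTN, Graphormer) and fixed-embedding heads, task-conditioned losses and
    Adam training on a built-in reverse-mode automatic differentiation engine,
    a metric suite (ROC-AUC, PR-AUC, macro F1, MSE, MAE, Spearman rho, R
    squared), and multi-seed benchmark comparison with Student's t tests.
    Seeded synthetic planted-motif generators emulate every task type so the
    full pipeline runs without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
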