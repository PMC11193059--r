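Package: seqdta
Title: Sequence-Only Protein-Ligand Binding Affinity Prediction with
    Dynamic Convolutional Embeddings and Split-Head Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity (-logKi/-logKd/-logIC50)
    from one-dimensional sequence inputs alone: the protein amino-acid
    sequence, an optional binding-pocket mask, and the ligand SMILES string.
    Sequences are label-encoded against fixed token dictionaries, embedded by
    a dynamic word-embedding layer (multi-kernel 1D convolution gated through
    a highway network), contextualised by stacked split-head self-attention,
    and combined through a protein-by-ligand cross-attention interaction map
    pooled into a fully connected regression head. Includes a from-scratch
    AdamW optimiser with decoupled weight decay, early stopping, k-fold
    cross-validation with ensemble-averaged prediction, the standard affinity
    evaluation metrics (RMSE, MAE, SD, concordance index, Pearson r), readers
    for FASTA, SMILES, pocket PDB and PDBbind-style index files, and a
    synthetic-data generator that plants a learnable pocket-by-ligand
    interaction signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
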