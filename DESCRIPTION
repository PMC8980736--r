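Package: surrodock
Title: Conformation-Agnostic Surrogate Models for Protein-Ligand Docking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains and applies fully connected neural-network surrogates
    that predict summary statistics of docking energies and binding
    affinity (pK) for a protein-small-molecule pair, using only a coarse
    voxelized representation of the binding pocket and the topology graph
    of the ligand. Includes pocket extraction and one-hot voxelization
    from PDB structures, fixed-size ligand graph encoding from SMILES
    with least-bond-order pruning, construction of regression targets
    from docking-run energy tables, a spectrally normalized residual
    regression network with reproducible training, a synthetic docking
    oracle for end-to-end validation, and batch virtual screening with
    Lipinski rule-of-five filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    ChemmineOB,
    ChemmineR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
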