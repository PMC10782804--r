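Package: dockgraph
Title: Interface Residue Graph Networks for Scoring Protein-Protein Docking Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts two-chain protein-protein complex structures into
    interface residue graphs with physicochemical, sequence-profile and
    protein language-model embedding node features, and scores docking
    models with a two-branch attention graph convolution network trained
    to predict the fraction of native contacts (fnat) or to classify
    biological versus crystallographic interfaces. Includes CAPRI-style
    structural quality metrics (fnat, interface and ligand RMSD, DockQ),
    ranking metrics (interpolated ROC/AUC, per-complex success rates),
    an HDF5 graph container, and a synthetic complex/decoy generator so
    the full pipeline runs at desk scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
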