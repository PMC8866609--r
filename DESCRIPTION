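Package: hemefold
Title: Hybrid Coarse-Grained Protein / Atomistic Heme Folding Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Energy model and sampling toolkit for heme proteins that couples a
    three-bead-per-residue coarse-grained protein representation to an
    atomistically represented heme b or heme c cofactor through knowledge-based
    interaction potentials: a coordinate-covalent Fe-residue restraint, screened
    electrostatics, backbone and sidechain hydrogen bonding to the heme
    carboxylates, a carboxylate burial penalty, excluded volume, and thioester
    attachment for heme c. Includes the Q_w and Q_c fraction-of-native-contact
    structure metrics, Kabsch RMSD, BAOAB Langevin dynamics with simulated
    annealing, Q_w-biased umbrella sampling, WHAM recombination, 2D free-energy
    surfaces, and a self-contained synthetic toy system (idealized planar heme
    plus a designable mini-globin) so everything is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
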