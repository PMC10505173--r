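Package: rnaforge
Title: Restraint-Driven Coarse-Grained RNA Tertiary Structure Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A restraint-driven folding engine for RNA tertiary structure
    built on a three-bead (P, C4', glycosidic N) coarse-grained
    representation with per-residue rigid frames.  Implements the frame
    aligned point error (FAPE) and binned geometry losses, cubic-spline
    hybrid potentials over inter-nucleotide distances and long-range
    dihedrals, gradient-based (L-BFGS) multi-start folding in frame space,
    full-atom reconstruction from bead models, and RNA model-quality
    metrics (P-RMSD, TM-score, interaction network fidelity, deformation
    index, handedness).  Includes a configurable-scale transformer /
    invariant-point-attention network trainable at toy scale, and an
    oracle module that emulates network restraints from reference
    structures so the folding stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
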