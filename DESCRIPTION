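Package: uvshape
Title: Rigid-Body Geometry and Elastic-Network Mode Analysis of
    Receptor-Transducer Quaternary Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing quaternary-structure transitions in
    two-protomer membrane receptor-transducer complexes such as the
    sensory rhodopsin II / HtrII photoreceptor module. Reads and writes
    PDB-format structures; performs Kabsch least-squares superposition
    with rotation axis/angle extraction; fits helix axes and measures
    inter-helix angles, piston displacements along the membrane normal
    and axial helix rotations; detects hydrogen bonds, salt bridges and
    steric clashes; builds Calpha elastic network models and computes
    normal modes both in full and with the rotation-translation-block
    (RTB) reduction; projects conformational transitions onto
    low-frequency modes (per-mode and cumulative overlaps, best-k mode
    combinations, mode-character classification); expands crystal
    symmetry mates for a small built-in space-group table and scores
    inter-mate packing contacts. Includes a synthetic-structure
    generator that plants known rigid-body rotations, piston shifts and
    lattice packings so that every estimator has an exact recovery test.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
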