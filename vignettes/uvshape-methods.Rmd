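---
title: "Methods: quantifying U/V quaternary transitions with uvshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying U/V quaternary transitions with uvshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvshape)
```

## The problem

Two-protomer membrane receptor–transducer complexes such as sensory
rhodopsin II with its transducer HtrII can crystallize in two quaternary
arrangements: a compact "U", with both receptors parallel to the
central transducer four-helix core, and a splayed "V" that opens toward
the cytoplasm. The U→V change has been proposed as the transmembrane
signalling step: each receptor rotates as a rigid body by a few degrees
about an in-membrane axis, and the transducer helix TM2 undergoes a
sub-ångström piston shift along the membrane normal together with a
rotation of tens of degrees about its own axis. This vignette describes
how `uvshape` measures each of these quantities, how its elastic-network
machinery tests whether the transition lies along soft collective
motions, and which design choices were open and how they were settled.

## Rigid-body superposition

`superpose()` implements the Kabsch solution: centre both paired
coordinate sets, take the SVD of the covariance `C = Xᵀ Y = U D Vᵀ`, and
form `R = V diag(1, 1, det(VUᵀ)) Uᵀ`. The determinant correction
excludes reflections by sign-flipping the smallest singular direction —
mandatory for protein coordinates, whose chirality must be preserved.
Collinear inputs (second singular value below `1e-10` of the largest)
and sets of fewer than three pairs are rejected as degenerate rather
than silently returning an arbitrary rotation.

The rotation angle is mathematically `acos((tr R − 1)/2)` but is
evaluated as `atan2(‖skew(R)‖/2, (tr R − 1)/2)`: the arc cosine loses
half its significant digits near 0° and 180°, and the identity-recovery
contract (angle `< 1e-6` degrees for noiseless inputs) is only
achievable with the arctangent form. Near 0° and 180° the axis itself is
geometrically ill-defined; it is still reported, with a `degenerate`
flag.

`relative_monomer_rotation()` composes two superpositions: first the
whole complexes are aligned on a *frame* selection, then the residual
rigid transform carrying one monomer onto its counterpart is extracted.
The choice of frame is not neutral — published monomer-rotation values
do not state it — so the frame is an explicit argument. For the
synthetic benchmark the natural exact frame is the pair of TM1 helices,
which no planted perturbation touches.

## Helix geometry

A helix axis from `fit_helix_axis()` starts as the dominant principal
direction of the centred Cα coordinates, but plain PCA is biased on
short helices: unless the trace covers a complete discrete period of
the 100° twist, the circular component leaks into the leading principal
direction (about 1° of tilt for a 20-residue helix). The estimate is
therefore refined by the second-difference construction: for an ideal
helix the second differences of consecutive Cα positions lie exactly in
the plane normal to the axis, so normalized cross products of successive
second differences give the axis with no partial-turn bias, and they
average away isotropic noise. `fit_rms`, the RMS distance of the Cα
atoms from the axis line, equals the helix radius (2.3 Å) on ideal
input and acts as a sanity check on real helices.

`piston_displacement()` projects the displacement of the Cα centroid of
a helix segment onto the membrane normal. The "cytoplasmic end" is
operationalized as the terminal 25 % of the residue ladder on the
intracellular side of the frame (configurable); which end that is gets
decided from the frame itself, so flipping the normal flips the
assignment consistently.

`helix_axial_rotation()` aligns the two helix copies' axes by the
minimal rotation between their directions, projects each residue's Cα
onto the plane normal to the axis, and returns the circular mean of the
per-residue angular displacements. Because translation along the axis
does not change those angles and an axial spin does not move the
centroid along the axis, piston and spin decouple exactly for planted
screw motions — a property test draws random θ ∈ [0°, 40°], d ∈ [0, 2] Å
and recovers both to 10⁻³.

Contact typing uses the standard structural-biology thresholds, none of
which the motivating literature states: hydrogen bonds at donor–acceptor
heavy-atom distance ≤ 3.5 Å with an antecedent–donor–acceptor angle
≥ 90° when hydrogens are absent, salt bridges at ≤ 4.0 Å between
oppositely charged side-chain terminal atoms (Lys NZ / Arg NH*, NE /
His ND1, NE2 versus Asp OD* / Glu OE*), steric clashes below 2.5 Å, and
generic contacts to 4.5 Å. All four are arguments. Cα-only models can
only support clash/contact kinds and say so with a warning.

## The elastic network and its RTB reduction

`enm()` builds the anisotropic network model: Cα nodes, uniform springs
γ = 1 between all pairs within a 10 Å cutoff. Neither the cutoff nor
the spring model is dictated by the motivating study, which names only
the model class; 10 Å with uniform γ is the common ANM default, and the
cutoff is an argument precisely because mode-character conclusions
should be checked against it. The Hessian assembles one 3×3
super-element `−γ d̂ d̂ᵀ` per contact, with diagonal super-elements equal
to minus the row sum, so the six rigid-body motions are exact zero
modes of a connected network by construction. Connectivity is checked
and reported: a disconnected model is not an error, but its zero-mode
count exceeds six and usually signals a cutoff that is too short.

`rtb_modes()` implements the rotation-translation-block reduction. Each
block (one residue, or one helix via `blocks_by_chain()`) contributes an
orthonormal basis of its rigid translations and rotations about the
block centroid — six columns, fewer for one- or two-node blocks whose
rank-deficient directions are dropped by SVD. Because the projection
matrix has orthonormal columns, the back-projected Cartesian modes are
orthonormal with no extra work, and each reduced eigenvalue bounds its
full-model counterpart from above (Rayleigh–Ritz); the test suite
asserts this domination index by index and checks that the one-node-
per-block limit reproduces the full spectrum. Zero modes are identified
by a relative threshold, eigenvalue < 10⁻⁸ × the largest (with an
absolute floor of 10⁻¹⁰ for the all-rigid edge case), which is robust
to the overall model scale. Mode signs are fixed by making each
vector's largest-magnitude component positive, so results do not depend
on the eigensolver's arbitrary sign choices.

## Projecting the transition onto modes

`transition_vector()` superposes V onto U over a frame selection (all
paired Cα by default; the transducer frame is the alternative worth
reporting alongside), and the displacement of the paired atoms gives
`rmsd_initial`. With orthonormal modes the best-k amplitudes are plain
projections, so `rmsd_initial² = explained² + residual²` holds to
rounding — the suite asserts 10⁻⁶ — and the cumulative overlap
`√Σᵢ₌₁ᵏ overlapᵢ²` is non-decreasing and capped at 1. Zero modes are
always excluded from overlap and fit indices: "the k lowest modes"
means the k lowest *nonzero* modes here. One subtlety: a finite rigid
rotation is not an infinitesimal one, so a planted rotation of 8.5°
carries a second-order component (fraction ≈ tan(4.25°) ≈ 7 % of the
displacement norm) that lies outside the rigid-block tangent space
entirely; completeness checks (`cumulative = 1` on the full basis)
therefore belong to the full Cartesian mode basis, not to the RTB
subspace.

`classify_mode()` fits each mode's restriction to a rigid group by an
infinitesimal rigid motion `t + ω × (r − c)` about the group centroid.
About the centroid the translation and rotation fields are orthogonal,
so the squared norm splits exactly into translation, rotation and
internal-deformation fractions, and `t · n̂` is the mode's piston
component along the membrane normal.

## The synthetic benchmark

The generator is the package's test bed, and its defaults are the
benchmark conditions: receptor rotation 8.5°, TM2 piston 0.5 Å toward
the cytoplasm, TM2 axial rotation 19° — the values reported for the
U→V transition of the sensory rhodopsin II / HtrII complex — with
optional isotropic Gaussian coordinate noise (the minimal stand-in for
coordinate uncertainty; no noise model is given in the literature).

The architecture is an idealized Cα complex: a central four-helix
transducer core on the C2 axis (TM helices of 26 residues at ±(4, 4) Å),
flanked by two three-helix receptors (22 residues each) whose bundle is
packed more tightly internally (6.4–8 Å centre spacing) than it is
coupled to the core (10 Å centre spacing). That deliberate asymmetry —
rigid subunits, soft interface — reproduces the qualitative mode
structure reported for the real complex, where the softest modes are
inter-subunit rotations and the U→V opening lies within the
low-frequency spectrum; with a uniformly coupled geometry the planted
opening would excite stiff interface modes instead and no low-mode
combination could compress it. The receptor tilt pivots about an
in-membrane axis through the receptor's intracellular end, matching the
proposed mechanism of a tilt about the intracellular receptor–transducer
contact, and the second protomer is the exact C2 image of the first, so
V remains C2-symmetric until the (asymmetric) piston is planted on one
TM2. Helices follow the textbook Cα parametrization — 1.5 Å rise, 100°
twist, 2.3 Å radius — giving a 3.830 Å Cα–Cα chord.

`scale_transition()` rescales a planted transition to an exact overall
RMSD (2.9 Å for the benchmark) while preserving its direction, which
lets amplitude-dependent quantities be compared at the literature scale.
What the generator does *not* emulate: side chains and sequence (so
hydrogen-bond/salt-bridge typing is exercised on separate hand-built
all-atom micro-fixtures), loops connecting helices, anisotropic
coordinate error, and lattice-induced strain. Recovery tests on this
generator therefore validate the estimators' correctness, not their
behaviour on crystallographic artefacts.

The lattice fixtures plant the packing argument: the "open" preset is an
isolated molecule in a 200 Å P1 cell (no mate approaches the probe);
the "tight" preset wraps the complex plus an appended two-helix
protrusion in a P2₁2₁2 cell whose c edge is shorter than the molecular
height by construction — offset by half the 1.5 Å Cα grid so the next
layer's TM2 runs through the appended domain with atoms interleaved at
≈ 2 Å — guaranteeing at least one steric clash while the in-plane screw
mates stay remote.

## Numerical choices and problem sizes

The benchmark complex has 236 Cα nodes (708 Cartesian DoF, 60 RTB DoF
with per-helix blocks), small enough that dense `eigen()` is exact and
the entire test suite, including twenty-seed noise studies, runs in
seconds; the acceptance script completes in well under a minute. Dense
symmetric eigendecomposition was chosen over sparse/iterative solvers
deliberately: at these sizes it is faster, deterministic, and free of
convergence tuning. Noise studies use σ = 0.1–0.2 Å; at σ = 0.2 Å the
planted 8.5° rotation is recovered with < 5 % bias over 20 seeds, and
the ten-mode residual fraction stays below 0.35 at σ = 0.1 Å.

## Known limitations

* The ENM parameterization underlying published mode-character claims
  is unstated in the motivating study; conclusions here are
  threshold-based (residual fractions, overlap bounds), not exact
  reproductions, and should be scanned over cutoffs (8–13 Å) on real
  structures.
* `read_pdb()` keeps only the first alternate location and ignores
  anisotropic displacement records; mmCIF is not supported.
* The space-group table covers only the groups relevant to the U/V
  packing argument plus P1; anything else requires an operator file.
* Infinitesimal-motion classification of modes degrades for groups
  smaller than ~5 nodes, and finite planted rotations are only
  first-order representable in any mode basis (see above).
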