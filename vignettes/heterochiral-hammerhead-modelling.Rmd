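---
title: "Modelling heterochiral hammerhead ribozyme complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterochiral hammerhead ribozyme complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralhh)
```

## The problem

Mirror-image (L-ribose) RNA is nuclease-resistant and non-immunogenic, which
makes L-oligonucleotide catalysts attractive; but an L-ribozyme acting on a
natural D-RNA substrate must form a *heterochiral* complex, whose helical
segments pair strands of opposite handedness. `chiralhh` implements the
modelling workflow behind that question for the hammerhead ribozyme: build a
homochiral D/D complex, derive its L/L mirror image, convert one strand in
place to obtain the heterochiral L/D (and its mirror D/L), and quantify what
the conversion does to Watson–Crick pairing and nucleotide conformation.

The package is an analysis toolchain, not a folding or dynamics engine. Its
contracts are geometric and topological: which pairs exist, which
donor–acceptor distances and base coplanarities are satisfied, what the
backbone torsions, glycosidic angles and sugar puckers are, and how all of
these transform under reflection.

## Data model and templates

A structure is a table of heavy atoms (hydrogens are never modelled) grouped
into chains of 1-based, 5′→3′ numbered residues. Ideal residue geometry is
pinned in one versioned file, `inst/extdata/residue_templates.csv`, derived
from the public PDB Chemical Component Dictionary ideal coordinates with
hydrogens and OP3 removed. Everything template-derived — atom sets, bond and
angle ideals for validation and refinement, and the D-reference signs of the
four sugar chiral centers — is computed from that file, so heavy-atom counts
are forced: bases contribute A=10, G=11, C=8, U=8 atoms, the
sugar–phosphate backbone 12 with a 5′-phosphate and 9 for the default free
5′-OH terminus. For the printed 14-nt substrate and 33-nt ribozyme this
yields 289, 711 and 1000 heavy atoms — totals the test suite pins.

## Parametric nucleotide construction

Sugar rings are built to a prescribed Altona–Sundaralingam pseudorotation
phase P and amplitude νmax (default 38°). The five endocyclic torsions obey
ν~j~ = νmax·cos(P + 144°(j−2)); the builder places the ring by natural
extension using two torsions, closes the last bond exactly, and Newton-iterates
until the *measured* (P, νmax) equals the target to 10^-6^ degrees. Phases
below a 5° amplitude floor are reported as undefined rather than noise. The
base is attached at a prescribed glycosidic χ (O4′–C1′–N9–C4 for purines,
O4′–C1′–N1–C2 for pyrimidines); rigid local offsets pinned from the template
encode the D configuration, so a built residue always classifies D and its
mirror image L.

## Ideal helices and the pinned placement parameters

Duplex generation follows the fiber-model idiom: an idealized Watson–Crick
pair, constructed once per pair type by least-squares placement of the two
planar bases at 2.9 Å donor–acceptor distances and dyad-symmetrized, is
carried along a helical screw. The helical parameters are pinned: A-form
32.7°/step twist, 2.81 Å/step rise, C3′-endo (P = 18°) sugars; B-form
36.0°, 3.38 Å, C2′-endo (P = 148°). The remaining placement parameters —
the pair's displacement from the helix axis and small per-class (purine vs
pyrimidine) glycosidic offsets that keep the O3′–P backbone step continuous
across mixed-sequence steps — were calibrated once against two contracts and
then frozen in `helix_form()`: every generated pair must pass 3D
Watson–Crick detection, and the mean adjacent intra-strand P–P distance must
come out at the canonical 5.9 Å (A-form, N-type sugars) and 7.0 Å (B-form,
S-type). The generator has a known ±0.1 Å sequence-composition bias around
those means (poly-G/C runs sit low); the tests therefore evaluate the
contract on a mixed-sequence decamer.

The hammerhead scaffold arranges the three stems as ideal A-form segments in
a three-way layout and places unpaired core, loop and dangling residues on
smooth Bézier arcs with a 2.5 Å clash floor. It is a topologically valid
analysis fixture — all mapped pairs detectable, all residues D, atom counts
exact — and explicitly *not* a physical fold prediction: core geometry,
stacking and junction angles carry no free-energy meaning.

## Mirror operations and chirality

The mirror operation negates z. Coordinate negation is exact in floating
point, so mirror∘mirror is the identity bitwise and all pairwise distances
are preserved exactly, while every torsion negates, P shifts by 180°, and
each sugar chiral center's signed volume — the scalar triple product over
its three ranked substituents — changes sign. A residue is D when all four
center signs match the template reference, L when all four are opposite,
invalid otherwise; a complex verdict is all-D, all-L, mixed, or invalid.
Validation also flags covalent geometry outside ±0.1 Å / ±10° of template
ideals, a deliberately lenient, MAXIT-like window.

## Heterochiral conversion and restrained refinement

One strand is converted in place: each residue is mirrored and rigidly
re-anchored (proper rotation only) onto its own pre-mirror base position.
Bases are planar, so this re-anchoring is numerically exact for the base
while the sugar flips its handedness — Watson–Crick partners keep facing
each other, and only the backbone needs repair. That repair is a restrained
gradient descent with backtracking line search (monotone energy trace by
construction, deterministic): harmonic bonds and angles toward template
ideals (O3′–P linkage 1.607 Å), H-bond harmonics at 2.9 Å, base-pair
planarity harmonics, signed-volume restraints that hold each sugar's current
handedness (the analogue of chirality-enforcing force-field impropers), a
0.05 Å per-step trust region, and gentle 0.5 kcal/mol·Å² position anchors
on paired-base heavy atoms. Module-level defaults are bonds 300, angles 50,
H-bonds 10, planarity 5 (kcal/mol units); the heterochiral conversion
strengthens H-bonds to 50 and planarity to 10 because the scaffold's
junction arcs exert enough tension to drag stem-end pairs out of the
detection window under the gentler constants. Anchors apply to every mapped
pair, including the intramolecular stem, whose terminal pair is pulled by
two arcs at once.

A generated duplex is *near* but not *at* the minimum of the restraint
energy (its strand junctions are approximate), so idempotence is asserted at
a converged structure — refining a refined structure changes it negligibly —
rather than on raw generator output.

## Force-field enantiomerization

Bond, angle and nonbonded terms are achiral and identical for both
enantiomers; only torsion phases and improper terms encode handedness. The
`enantiomerize()` operation negates the chirality-defining signed parameter
of every term — δ → (−δ) mod 360° for periodic torsions and impropers
(0° and 180° are fixed points), ξ0 → −ξ0 for harmonic impropers — leaving
force constants and periodicities untouched. This is the unique sign rule
under which the torsion-plus-improper energy is exactly invariant when the
structure is mirrored and the parameters enantiomerized simultaneously
(φ → −φ cancels δ → −δ); negating a force constant instead would either
flip the energy's sign (periodic form) or make it unbounded (harmonic form).
The evaluator demonstrates the invariance to 10^-9^ relative on generated
fragments, and the strict non-invariance of D parameters applied to an L
structure whenever some phase lies outside {0°, 180°}.

## Ensembles and statistics

The ensemble generator emulates the statistical shape of an MD ensemble: per
frame and residue it resamples P and χ from wrapped normal distributions
(defaults: 200 frames, σ~P~ = 8°, σ~χ~ = 10°, 0.05 Å coordinate noise —
magnitudes typical of stable helical nucleotides in room-temperature
simulations) and rebuilds the residue on its fixed base. It reproduces
prescribed per-residue conformer statistics and exact mirror relationships;
it does **not** model correlated motions, backbone continuity under extreme
resampling, rare-event transitions, or solvent/ion effects, so passing
recovery tests certifies the analysis operators, not any dynamical realism.

Circular statistics use the wrapped-median definition (minimizer of the
mean absolute circular deviation). When the minimizing set is an arc — as
for even sample sizes — the arc midpoint is returned, which keeps the median
exactly antisymmetric under data negation so that mirror symmetry propagates
exactly through ensemble summaries. Quartiles are quartiles of wrapped
deviations about that median. Superpositions are Kabsch fits; with
reflections disallowed (the default, determinant forced to +1) enantiomers
compare at a nonzero RMSD, while allowing reflections makes that comparison
trivially zero — heterochiral comparisons therefore default to
proper-rotation-only. The ribose-phosphate backbone selection used by RMSD
series excludes O2′ by default (configurable).

## Numerical choices

- Torsions live in (−180°, 180°] (−180° maps to +180°), phases P in
  [0°, 360°); syn/anti boundary at |χ| = 90° with the boundary assigned to
  anti; N = P ∈ [315°, 45°), S = P ∈ [135°, 225°), 18° conformer bins.
- All randomness flows through explicit integer seeds (one per operation or
  one root seed split per pipeline stage); no global RNG state is disturbed.
- The sizes used by the shipped tests — 6–10 bp duplexes, the 47-nt
  scaffold, 200-frame ensembles of a 4-bp duplex, 300–500 refinement
  steps — were chosen as the smallest problems that exercise every contract.

## Known limitations

Junction and loop geometry is heuristic; B-form parameters describe a
generic S-type duplex rather than any fitted fiber model; the refinement
energy is a restraint potential (no electrostatics, stacking or sterics
beyond the clash floor); modified nucleotides, proteins, ions and solvent
are out of scope; and absolute RMSD values between independently built
models depend on construction conventions and are reported for protocol
comparisons, not as physical observables.
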