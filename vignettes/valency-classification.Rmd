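---
title: "Classifying receptor homodimer conformations as monovalent or bivalent-competent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying receptor homodimer conformations as monovalent or bivalent-competent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalens)
```

## The question and the procedure

A homodimeric receptor with two open binding sites is not automatically
bivalent.  When the ligand is an elongated tandem-domain molecule bound at
the membrane-distal tip of each subunit, the *orientation* of the two
subunits decides whether two simultaneously bound ligands would collide at
their membrane-proximal (carboxy-terminal) domains.  CD28 and CTLA-4 are
the motivating pair: structurally near-identical monomers, but a compact
dimer orientation in one case (sterically monovalent) and an open one in
the other (bivalent).  For a conformational ensemble of the dimer the
interesting quantity is therefore the *fraction of frames that could bind
bivalently*.

`bivalens` computes that fraction in four strictly geometric steps per
frame:

1. **Template docking.**  A binding-mode template (one receptor monomer
   plus one ligand, in the known bound pose) is superposed onto each
   monomer of the frame with a Kabsch least-squares fit over a declared
   atom selection, and the ligand is carried along by the fitted rigid
   transform.  No flexibility, repacking or scoring is involved; the
   procedure assumes the binding mode itself is conserved across
   conformers, which is exactly the assumption the analysis is designed to
   exploit (the *receptor dimer geometry*, not the binding interface, is
   what varies).
2. **Buried surface.**  The solvent-accessible surface area buried between
   the two docked ligands' scoring selections,
   $\mathrm{BSA} = \tfrac12\,(A_1 + A_2 - A_{12})$, with each SASA term from
   the Shrake–Rupley test-point method.
3. **The zero rule.**  $\mathrm{BSA} = 0$ means the two docked ligands do
   not occlude each other at all, so nothing prevents double occupancy:
   the frame is *bivalent-competent*.  Any positive buried surface is a
   steric clash of the rigid ligand copies.
4. **Aggregation.**  Per-trajectory fractions of bivalent-competent
   frames, and their unweighted arithmetic mean across independent
   trajectories.

The classifier is deliberately binary.  The magnitude of a positive
buried surface measures how deeply two rigid copies interpenetrate, which
has no physical interpretation beyond "clash"; only the zero/nonzero
distinction carries meaning, which is also why the per-side factor
$\tfrac12$ in the BSA convention is immaterial to the result.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `probeRadius` | 1.4 | Å | water probe for all SASA terms |
| `nSpherePoints` | 960 | – | Shrake–Rupley test points per atom |
| `zeroTolerance` | 1.0 | Å² | buried area at or below this counts as zero |
| `rmsdCeiling` | 3.0 | Å | docking fit RMSD above this flags the frame |
| `scoringMode` | `cterm_domain` | – | score C-terminal domains or whole ligands |
| `frameStride` | 1 | – | sample every n-th frame |
| radii | C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 | Å | standard van der Waals set, table-configurable |

Choices worth explaining:

* **960 test points** put the discretisation error of a single
  atom-pair overlap well under one percent (the suite checks a 20-atom
  body against a 10^5-point brute-force integrator at 2%, and halving the
  point spacing moves the total by less than 1%).  The point set is a
  deterministic golden-section spiral, so every SASA number is bit-for-bit
  reproducible.
* **`zeroTolerance` = 1 Å²** exists because a discretised SASA can report
  a fraction of a square Ångström of "burial" for groups that graze the
  occlusion bound.  The geometry of the exact-zero guarantee: when every
  cross-group atom pair is separated by more than
  $r_i + r_j + 2r_\mathrm{probe}$, neighbour pruning makes the per-atom
  areas in the complex bitwise identical to the isolated ones and the
  difference is exactly zero, not merely small.  The boundary of the rule
  is inclusive (`buried <= tolerance` is bivalent).
* **C-alpha fit atoms** are the default for superposition, docking and
  RMSD.  The underlying MD analyses this mirrors do not state their atom
  sets, so the package exposes the selection everywhere and defaults to
  the most robust conventional choice; an all-heavy-atom fit is one
  selection away.  Flexible segments (a membrane-proximal stalk, say) are
  excluded the same way — by residue-range selection.
* **Unweighted trajectory averaging**: the headline statistic is the
  plain mean of per-trajectory fractions (three trajectories with
  fractions 0.10/0.30/0.38 average to 0.26), treating each independent
  trajectory as one observation regardless of length.  The frame-weighted
  pooled fraction is reported alongside for comparison.
* **`rmsdCeiling`** is quality control, not filtering: a monomer so
  distorted that the template fit exceeds the ceiling gets a warning and
  a flag on its record, and summaries count flagged frames per
  trajectory, but the frame is never silently dropped.

## Dimer geometry: descriptors and builds

`describeDimer()` reduces a conformer to four scalars: binding-site
centroid separation, interface-anchor centroid gap, the opening angle
between the monomer principal axes (each axis sign-oriented from the
interface-anchor centroid toward the binding-site centroid), and a twist
(the dihedral of the two binding-site centroids about the inter-anchor
axis).  The interface axis is *defined* as the line through the two
interface-anchor centroids — the anchors being user-supplied selections
such as the charged residues at the base of the dimer interface — because
no more canonical definition exists for an arbitrary dimer.

Two constructions produce alternative starting conformations:

* `graftOntoDimerTemplate()` superposes rigid copies of a monomer onto
  each subunit of another dimer, adopting that dimer's subunit
  orientation (the "rebuild the compact dimer in the open orientation"
  experiment).
* `reorientDimer()` rotates one whole chain about the interface axis by a
  caller-chosen angle, then *enforces* that every residue of a declared
  interface selection retains a heavy-atom contact within
  `contactCutoff` (default 5 Å) of the partner chain, rejecting builds
  that lose the interface and naming the lost residues.  The rotation
  angle is a parameter, not a constant: the source analyses describe the
  rotated conformation qualitatively, so the package documents a sweep
  rather than pretending to a canonical value.

Both builds are exactly rigid (internal distances preserved to numerical
precision), and `describeDimer()` of a reoriented parallel-axis toy dimer
shifts its opening angle by exactly the applied rotation — one of the
acceptance properties.

## What the synthetic generator emulates — and what it does not

`makeToySystem()` builds a minimal geometric analogue of the biological
system: an elongated monomer (a 60-atom deterministic lattice rod, 30 Å
long, lattice radius 3 Å) and a tandem two-domain ligand (two 24-atom
quasi-spherical shells of radius 3 Å, centres 12 Å apart, the distal one
standing 6 Å off the monomer tip).  `makeDimerFrame()` places two monomer
copies about an exact C2 axis with a controllable opening angle and twist
plus an interface offset of 2 Å at the base.  The rod lattice is built
from antipodal atom pairs so its first principal axis is exactly the rod
axis, which turns the opening-angle properties from approximations into
identities.

The geometry is chosen so the classifier's decision boundary is crossed
by the opening angle alone: the C-terminal domain centroid of a docked
ligand sits 48 Å from the dimer base, so the two domains' centroid
separation is $s(\theta) \approx 2\cdot 48\,\sin(\theta/2) + 2$ Å.  At
the compact regime mean (5°) the domains interpenetrate deeply
(~100 Å² buried); at the open regime mean (80°) they clear the occlusion
bound $2(r_\mathrm{max}+r_\mathrm{probe}) = 6.2$ Å by over 50 Å.  Ground
truth per frame is computed independently of the pipeline, from the exact
construction transforms applied to the template ligand (minimum
cross-domain atom distance versus the occlusion bound), with the margin
recorded per frame.  In two-regime mode every frame clears the bound by
several Ångström on its own side — orders of magnitude beyond the
1 Å² tolerance — so classifier agreement with ground truth must be exact,
and programmed fractions (a target fraction rounded to a whole frame
count, order shuffled by seed) must be recovered exactly.  The default
atom jitter (0.05 Å, i.i.d. Gaussian) is negligible against these
margins; it exists to keep frames from being bit-identical.

What the toy does *not* emulate: protein chemistry.  The bodies are atom
clusters, not chains; there is no force field, no solvent, no side-chain
packing, no realistic binding interface, and the "trajectories" are
i.i.d. draws, not time-correlated dynamics.  Passing tests therefore
demonstrate that the *geometric pipeline* — parsing, superposition,
docking, surface burial, classification, aggregation — is correct and
deterministic.  They say nothing about whether any particular receptor's
MD ensemble is 26% or 81% bivalent; that depends on the simulations fed
in, which are outside the package.  Randomness everywhere derives from a
caller-supplied integer seed through a fixed, recorded generator
("Mersenne-Twister/Inversion"), so all synthetic results are reproducible
across platforms.

## Numerical choices and degenerate inputs

* **Kabsch reflection branch**: the SVD sign is corrected by flipping the
  smallest singular vector, so returned rotations always have determinant
  +1, including for near-planar point sets.  Collinear point sets (rank
  < 2) and fewer than three points raise degeneracy errors rather than
  returning an arbitrary rotation.
* **Alt-locs** resolve to the highest-occupancy record, ties broken by
  file order; insertion codes are preserved and are part of residue
  identity.  HETATM and water records are dropped by default.
  Multi-model files are verified to share atom identities across models
  (a permuted model is a topology error, not a silent misassignment).
* **Coordinates** are fixed-format: the writer refuses values outside the
  PDB field range rather than corrupting columns, and round-trips
  reproduce coordinates to the format's 0.001 Å.
* **Empty selections are errors**, never empty results — a silently empty
  selection would corrupt every downstream RMSD and SASA.
* **Coincident atoms** in a SASA computation warn (degenerate geometry)
  but still yield defined areas.
* **Buried-surface clamping**: the union SASA is summed group-wise in the
  same order as the standalone sums, so full separation cancels exactly;
  residual magnitudes below 1e-9 Å² are snapped to zero and negative
  round-off is clamped.

## Problem sizes

The validation suite runs at deliberately small scale, chosen to exercise
every code path in seconds: toy bodies of 60 + 48 atoms, ensembles of
100–200 frames for fraction recovery (targets 0, 0.25, 0.5, 0.75, 1),
a 19-step opening-angle sweep (0–90° in 5° steps), 100–200 random cases
per superposition/docking property, 20 random bodies against the
dense-grid SASA oracle at 10^5 points per atom, and 100 random separated
configurations for the exact-zero property.  `scripts/acceptance.R`
re-runs the same computations from a command-line seed.

## Known limitations

* Docking is rigid by construction; receptors whose binding mode itself
  changes between conformers violate the template assumption.
* The SASA implementation is Shrake–Rupley only; solvent-excluded
  (Connolly) surfaces and per-residue decompositions are out of scope.
* Atom pairing for docking and grafting matches on residue number,
  insertion code, residue name and atom name — renumbered or mutated
  monomers need a selection that restricts both sides to the common atoms
  first; no sequence alignment is performed.
* Fractions carry no error bars beyond the spread across trajectories;
  block averaging and conformer clustering are intentionally absent.
* mmCIF and binary trajectory formats are not read; convert to
  multi-model PDB upstream.
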