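# bivalens

Frame-by-frame valency classification of receptor homodimer
conformational ensembles.

## The problem

Several immunoglobulin-superfamily cell-surface receptors (CD28 and its
inhibitory homologue CTLA-4 are the canonical pair) are expressed as
homodimers with two open ligand-binding sites, yet differ in whether they
can actually engage two copies of their shared, elongated two-domain
ligand (CD80/CD86) at once.  The difference is purely geometric: the
ligand binds at the membrane-distal tip of each subunit, and in a compact
dimer orientation the two bound ligands collide at their membrane-proximal
(carboxy-terminal) domains, limiting the dimer to monovalent binding.  A
more open subunit orientation removes the steric clash and permits
bivalent, high-avidity binding.

`bivalens` implements the structural readout of that distinction for
conformational ensembles (e.g. MD trajectory snapshots saved as
multi-model PDB files):

1. **Template docking.**  A binding-mode template — a receptor-monomer +
   ligand complex — is rigidly superposed onto each monomer of every dimer
   conformer (Kabsch least-squares fit over a declared atom selection) and
   the template ligand is carried along by the fitted transform.
2. **Buried surface.**  The solvent-accessible surface area (SASA,
   Shrake–Rupley) buried between the two docked ligands' carboxy-terminal
   domains is computed:

   `BSA = (SASA(A) + SASA(B) − SASA(A ∪ B)) / 2`

3. **The zero rule.**  `BSA = 0` means the docked ligands do not touch, so
   the conformation is *bivalent-competent*.  A frame is scored bivalent
   when its buried area is at or below a small tolerance (default
   1 Å², absorbing test-point discretisation noise).
4. **Aggregation.**  Per-trajectory bivalent fractions and their
   unweighted mean across independent trajectories.

The package also ships the dimer-geometry toolbox used to build
alternative starting conformations (graft a monomer onto another dimer's
subunit orientation; rotate one subunit about the interface axis while
verifying the interface residues stay in contact) and a seeded synthetic
toy-dimer generator with closed-form ground truth, so the entire pipeline
is testable without MD trajectories or structure downloads.

## Worked example

Three synthetic 100-frame trajectories with programmed bivalent fractions
0.10, 0.30 and 0.38, classified end to end:

```r
library(bivalens)

sys <- makeToySystem()          # toy monomer, two-domain ligand, template
sel <- sys$selections

gens <- lapply(1:3, function(i) generateToyEnsemble(sys, ensembleSpec(
  nFrames = 100, bivalentFractionTarget = c(0.10, 0.30, 0.38)[i],
  seed = i, trajectoryId = paste0("traj-", i))))

recs <- lapply(gens, function(g)
  analyzeEnsemble(g$ensemble, sel$monomer1, sel$monomer2, sys$template))

summarizeValency(recs)
```

```
Ensemble valency summary
  traj-1: 0.100 bivalent-competent (100 frames, 0 dock-quality flagged)
  traj-2: 0.300 bivalent-competent (100 frames, 0 dock-quality flagged)
  traj-3: 0.380 bivalent-competent (100 frames, 0 dock-quality flagged)
  mean over trajectories (unweighted): 0.260
  pooled (frame-weighted): 0.260
  zero tolerance: 1.00 A^2
```

Each per-frame record carries the buried area, the flag, and the two
docking fit RMSDs:

```
  trajectory_id frame_index buried_area_A2 bivalent_competent
1        traj-1           0       104.7869              FALSE
2        traj-1           1       105.7304              FALSE
3        traj-1           2         0.0000               TRUE
```

Compact frames bury ~100 Å² between the docked ligands' C-terminal
domains (a hard steric clash: monovalent only); open frames bury exactly
zero (bivalent-competent).  The unweighted mean over the three
trajectories, 0.260, is the headline ensemble statistic.

A command-line wrapper over the same functions is installed at
`inst/exec/bivalens`:

```sh
Rscript inst/exec/bivalens synth --out bundle --n-frames 100 --target-fraction 0.5 --seed 1
Rscript inst/exec/bivalens run  --ensemble bundle/ensemble.pdb \
    --template bundle/template.pdb --template-config bundle/template_config.txt \
    --config bundle/pipeline_config.txt --out results
```

writing `records.csv` (one row per frame) and `summary.json` (fractions,
mean, tolerance, config echo), byte-identically across repeat runs.

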