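# poreGating

Trajectory post-processing for hexameric ion channels of the Orai/CRAC
family. Given a topology (PDB/GRO) and a trajectory (DCD or multi-model
PDB) of a homo-hexamer, the package computes the geometric and occupancy
statistics used to compare channel variants — for example a wild-type
channel against a constitutively open gain-of-function mutant — and
classifies frames into gate states. A synthetic channel-trajectory
generator with exact programmable ground truth makes every statistic
verifiable at desk scale, without running molecular dynamics.

## What it computes

**Pore radius profile (HOLE-style).** With heavy-atom van der Waals radii
assigned (Bondi by default; hydrogens removed), the pore radius at height
*z* along the channel axis is

    radius(z) = max_p min_i ( ||p - x_i|| - r_i )

the largest probe sphere centred in the plane at *z* whose surface clears
every atom sphere. The maximiser is found by a deterministic coarse-grid
scan plus multi-start Nelder-Mead refinement, constrained to an escape
disk around the axis; it is validated against an exhaustive 0.02 Å grid
search. The **gate radius** is the windowed minimum of the profile around
the gate ring (K163 in Orai numbering), and frames with gate radius < 2 Å
are classified *closed*, otherwise *dilated*.

**Side-chain rotation statistics.** Two per-subunit angles on the XY
plane (viewed from the extracellular side, +z):

- *Rotation angle of residue 210* (TM2 mutation site): the signed angle
  between the Cα→pore-centre vector and the Cα→Cγ vector,
  clockwise-positive, so a side chain pointing at the pore reads 0° and
  the gain-of-function rotation reads about +50°.
- *Orientation angle of residue 171* (hydrophobic gate): the angle at
  vertex **b** (the geometric centre of the Cα atoms of residues 169–173)
  between **b**→pore-centre and **b**→Cα(171), counter-clockwise
  positive.

Angle distributions are converted to free-energy profiles by Boltzmann
inversion, ΔF = −k_B·T·ln p at 310 K.

**Occupancy.** Water oxygens are counted per frame in a 5 Å cylinder
bounded by the residue-171 and residue-178 Cα rings; Na⁺ and Cl⁻ in a
10 Å cylinder bounded by residues 148 and 184. Ion positions accumulate
into 3D density grids exported as OpenDX. Ring radii (e.g. the K270
ring), Cα-RMSD series (Kabsch superposition, reported in nm), average
structures and per-subunit contact distances (residue 210 vs 166)
complete the report.

## Worked example

Generate a wild-type-like and a mutant-like synthetic pair (60 frames
each) and run the full pipeline:

```r
library(poreGating)
specs <- exampleVariantSpecs(nFrames = 60, seed = 42)
trW <- generateTrajectory(specs$wild)
trM <- generateTrajectory(specs$mutant)
res <- runPipeline(list(variants = list(wild   = list(trajectory = trW),
                                        mutant = list(trajectory = trM))))
res$datasets$sizes
#>    wild-closed   wild-dilated  mutant-closed mutant-dilated
#>             40             20             21             39
```

The wild-type-like channel is mostly closed, the mutant-like channel
mostly dilated, as programmed. The per-variant summary shows the
mutant's higher hydration, deeper Na⁺ occupancy and dilated TM3 ring:

```r
s <- res$summary$variants
#> wild:   water 15.8  Na 7  Cl 16  K270 12.32 A  F210 modal 2.5
#> mutant: water 17.2  Na 9  Cl 15  K270 13.32 A  F210 modal 47.5
```

The rotation-angle modal bin moves from ~0–5° (wild, one of two equally
stable states) to ~50° (mutant), and the state-conditioned orientation
angle of the mutant-dilated set sits ~20° above the other three sets
(modal bins 37.5/37.5/42.5/62.5°) — the programmed gating contrast.

With file inputs, the same run is driven by a YAML config
(`runPipeline("run.yaml")`) or the bundled CLI
(`inst/scripts/poregating-cli.R`), which also exposes `simulate`,
`rmsd`, `profile`, `angles`, `occupancy`, `density` and `classify`
subcommands.

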