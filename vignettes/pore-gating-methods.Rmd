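---
title: "Methods: pore geometry, rotation statistics and gating-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore geometry, rotation statistics and gating-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poreGating)
```

poreGating post-processes molecular dynamics trajectories of hexameric
ion channels (Orai/CRAC-type) to quantify the geometry and occupancy
signatures of gating: pore radius profiles and gate-state classification,
two side-chain angle statistics with Boltzmann-inversion free energies,
water and ion occupancy, ring radii, RMSD series and contact distances.
This vignette documents the model behind each statistic, the parameters
that matter, the numerical choices, and what the bundled synthetic
generator can and cannot certify.

## Coordinate conventions and assumptions

All internal lengths are Angstrom; RMSD alone is reported in nm, the unit
in which it is conventionally plotted. The channel axis is assumed
pre-aligned with +z pointing extracellular, and coordinates pre-wrapped
(the pore sits at the box centre in typical membrane set-ups), so no
periodic-image handling takes place inside analysis cylinders. The pore
centre of a frame is the unweighted mean of the Cα positions of the TM1
residue range (default 144–180) over all six subunits; an optional
principal-axis mode exists for unaligned inputs and logs a message when
used. Chains identify subunits; GRO files carry no chains, so subunits
are inferred from residue-number periodicity (each drop in the running
residue number opens a new chain) and the inference is reported.

## Pore radius profile

At each height $z$ on a uniform grid (default step 0.5 Å), the pore
radius is the largest probe sphere centred in that plane whose surface
clears every heavy-atom van der Waals sphere:

$$R(z) = \max_{\|p - a\| \le E} \; \min_i \left( \lVert p - x_i \rVert - r_i \right),$$

with full 3D distances (atoms above and below the slice constrain it),
hydrogens excluded, and the probe confined to a disk of radius $E$
(escape limit) around the axis $a$ so it cannot leak through lateral
inter-helix gaps. vdW radii default to the Bondi set, shipped as a YAML
table (`inst/extdata/vdw_bondi.yaml`) so a force-field-derived set can be
swapped in; hydrogen identification accepts element "H" or atom names
starting H/1H/2H/3H, which is robust across PDB dialects.

The maximiser is deterministic, not simulated annealing: a coarse grid
scan over the disk (step $\min(0.5, E/8)$ Å, points outside the disk
clipped to its boundary) seeds the best three cells, which join the
axis, the previous slice's probe centre and eight perimeter points as
starts for Nelder-Mead refinement. The objective projects out-of-disk
probe positions onto the disk boundary, keeping it continuous there —
maxima of random atom clouds frequently sit exactly on the boundary, and
a hard penalty would stall the simplex. Each start's refined value is
floored at the start's own clearance, so the search improves
monotonically; ties between starts are broken toward the probe centre of
the previous slice, which keeps profiles smooth through near-degenerate
slices. A slice with no positive clearance is recorded as radius 0 and
flagged `blocked`. The independent oracle, `gridSliceRadius()`, is an
exhaustive 0.02 Å grid search; the test suite and the acceptance script
require agreement within 0.05 Å on random ≤50-atom configurations and
within 0.01 Å of the analytic single-ring value $R_{\mathrm{ring}} - r$.

**Gate radius** is the minimum of the profile within ±3 Å (configurable)
of the mean Cα z of the gate residues, because the constriction is formed
by side chains whose z offsets from their Cα plane vary. The per-frame
gate search uses a smaller default escape limit (5 Å) than full profiles
(12 Å): the constriction search belongs in the pore lumen, and a wide
disk would let the probe wander into gaps between helices that are not
pore-facing. Both limits are exposed as configuration.

## Gate-state classification

Frames with gate radius strictly below 2.0 Å are *closed*; radii at or
above the threshold are *dilated*. The boundary case (exactly 2.0 Å) is
assigned to dilated — the verbal definition ("less than" closed, "more
than" dilated) leaves equality undefined, and the convention is echoed
into every report header. Non-finite gate radii exclude the frame with a
message rather than silently entering a state. Two variants' label
vectors partition into four datasets (variant × state); the partition
identity (closed + dilated = total per variant) is asserted on every
construction.

## Side-chain angle statistics

*Rotation angle of the mutation-site residue (210).* On the XY plane,
$u$ points from Cα(210) to the pore centre and $v$ from Cα(210) to
Cγ(210). The statistic is the signed angle from $u$ to $v$ with
**clockwise positive when viewed from the extracellular side**, so "side
chain points at the pore" reads 0° and the gain-of-function rotation
reads about +50°. The source figure does not fix the red vector's
direction or the handedness; this choice makes the verbal "rotates
clockwise by about 50°" read as +50°, and the convention string is
attached to every angle series.

*Orientation angle of the hydrophobic-gate residue (171).* On the XY
plane, $a$ is the projected pore centre, $b$ the projected geometric
centre of the Cα atoms of residues 169–173 of the subunit (the window is
read as backbone Cα of the caption's parenthetical; a heavy-atom variant
is available by configuration), and $c$ the projected Cα(171). The
statistic is the signed angle at vertex $b$ from $b{\to}a$ to $b{\to}c$,
counter-clockwise positive viewed from +z, so the documented
counter-clockwise rotation increases the value. The rotation angle is
reported signed in (−180, 180]; the orientation angle is reported as its
absolute value (as it is conventionally plotted), with the signed value
retained in the series. Projections shorter than 10⁻⁶ Å make the angle
undefined: the value is NA, never silently 0, and histogram construction
reports how many entries were dropped.

The pore centre entering both statistics is recomputed per frame by
default (whether the original analysis fixed it from an average structure
is unstated; both modes are supported).

## Histograms and free energies

Angle histograms use 5° bins by default, matching the granularity at
which the gating intervals are usually quoted (e.g. 35–40°, 45–65°);
bins are half-open $[lo, hi)$ with edges on multiples of the bin width,
and probabilities are counts over retained entries, summing to one.
Boltzmann inversion gives $\Delta F = -k_B T \ln p$ at 310 K
(physiological, matching the simulation thermostat), shifted so the
minimum is zero; zero-probability bins are undefined (NA), not zero. The
closed-form two-state identity
$\Delta F = k_B T \ln\!\big(\tfrac{1-p}{p}\big)$ is enforced to 10⁻⁹
relative error in the tests.

## Occupancy and density grids

Water is counted as oxygen atoms of water residues (TIP3/SOL/WAT/HOH
dialects), ions by residue/atom name (SOD/NA, CLA/CL). The water
cylinder has a 5 Å radius between the residue-171 and residue-178 Cα
rings; the ion cylinder a 10 Å radius between residues 148 and 184. The
bounding-ring z values are recomputed every frame from the mean Cα z
over subunits (the bounding atoms are not named in the source; Cα is the
configurable default). Boundary conventions are inclusive (≤) on both
radius and z — counts are integers and the tests compare them exactly.
Counts never decrease when the cylinder is enlarged, and counting is
invariant under rigid motions applied jointly to atoms and region; both
are property-tested.

Density grids accumulate mean counts per voxel per frame; the voxel sum
equals the mean in-box count per frame to 10⁻⁹ (conservation), before the
optional per-Å³ normalisation. Both normalisations exist because
isosurface levels quoted for such maps (e.g. 0.02/0.06) are meaningless
without a unit statement; the OpenDX export records the mode in a header
comment.

## The synthetic generator: what it emulates, and what it does not

`syntheticChannelSpec()` describes an idealised C₆-symmetric channel:
one Cα ring per annotated residue at programmed radius and height, the
gate ring following a per-frame clearance schedule (atoms at radius
clearance + vdW so the analytic pore radius at that z *is* the
schedule), Cγ(210) placed 2.5 Å from Cα in the XY plane at the scheduled
clockwise angle with a fixed small +z offset (only the XY projection
enters the statistic), and a 169–173 Cα arc whose four flanking atoms
compensate the displacement of Cα(171) so the window centre stays on the
symmetric ring whatever the angle — this is what makes both angle ground
truths exact and keeps the pore centre independent of the schedules.
Water counts are Poisson by default, with an explicit two-component
Poisson mixture to emulate bimodal hydration and a fixed mode for exact
tests; ions are fixed counts (or Poisson) placed near the selectivity
filter (Na⁺) and the basic region (Cl⁻). Pool atoms not used in a frame
are parked far outside every analysis region, since topologies must keep
a constant atom count. Placement keeps a 0.75 Å margin inside the
counting cylinders so that the default 0.2 Å coordinate noise (a typical
heavy-atom thermal fluctuation scale) does not move particles across
counting boundaries. Isotropic Gaussian noise is added last; each frame
reseeds deterministically from (spec seed, frame index), so single frames
are reproducible in isolation and identical specs give byte-identical
trajectories.

Default conditions follow the wild-type closed channel: gate clearance
1.5 Å (dilated frames use 2.5 Å), rotation angle peaks at 5° and 50°
with equal weights, orientation angles near 40° (shifted +20° in
mutant-dilated frames), Poisson(16) pore waters (mutant: mixture of 12
and 21, mean ≈ 18), 7/9 Na⁺ and 16/15 Cl⁻, TM3 ring radius 12.30 Å
(mutant 13.33 Å), closed fractions 10123/15000 and 5175/15000. Ring
radii default to a closed-structure-like ordering (filter ≈ 3 Å
clearance, gate narrowest, basic region wider); they are configuration,
not claims about the real protein.

The generator is *not* a physical simulator: no force field, no time
correlation between frames (one frame = one saved snapshot; the analyses
are distributional), no membrane, no electrostatics, and a wall made of
isolated rings rather than continuous helices. Passing tests therefore
certify the *statistics* — that the estimators recover programmed
geometry, angles and counts under realistic coordinate noise — not that
the physics of any real channel is reproduced. Real-trajectory features
such as autocorrelation, anisotropic fluctuations, side-chain rotamer
jumps and imperfect hexamer symmetry are outside what these fixtures
exercise.

## Pipeline windows and sizes

`runPipeline()` mirrors the usual analysis layout: RMSD over full
trajectories against the first frame; the average structure (Kabsch on
Cα, frames superposed onto the first window frame) and its radius
profile over the equilibrated window — by default the last 40% of
frames, the analogue of analysing the last 200 ns of 500 ns; occupancy,
grids, ring radii and contacts over the same window; angle distributions
over the full trajectory (their windows are separate configuration
keys). Equilibration detection is deliberately *not* automated: the
window is explicit configuration, replacing a visual judgement. Multiple
trajectories per variant are pooled for distributions. Every derived
convention (signs, boundary, windows, atom choices) is echoed into the
summary JSON for provenance, and reruns on identical inputs are
byte-identical.

The test suite and acceptance script run deliberately small problems —
100 random ≤50-atom profiler configurations, 1000-frame noisy angle
recovery, 150-frame two-variant end-to-end runs — chosen so the whole
validation completes in minutes on one CPU while still leaving the
statistical checks (3-standard-error recovery, modal-bin placement
within one bin width) well-powered.

## Known limitations

DCD and multi-model PDB are the supported trajectory formats; XTC
requires a compressed-coordinate reader that no available R backend
provides, and raises an explicit error. The PDB writer emits fixed-width
records with serials and residue numbers wrapped at their column widths,
so structures beyond 99,999 atoms round-trip with wrapped serials.
Insertion codes and altLocs beyond the first are not handled, boxes are
orthorhombic, and no topology formats (PSF/TOP) are read. The profiler
reports geometry only — no conductance estimates — and the pipeline
reports distributions without statistical tests between variants.
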