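---
title: "Methods: trajectory observables for kinase activation-loop dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory observables for kinase activation-loop dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btkloop)
```

`btkloop` computes the observable set with which MD studies of kinase
domains characterise activation-loop (A-loop) remodelling, and compares
wild-type against mutant ensembles run-by-run. This vignette is the
package's own account of the underlying methods: the models and formulas,
the parameters that matter, the numerical choices, what the synthetic
benchmark does and does not establish, and the known limitations.

## Coordinates, addressing, units

Coordinates are Angstrom everywhere; criteria quoted in nanometres in the
literature are converted once at configuration time (0.35 nm → 3.5 Å,
0.4 nm → 4.0 Å, 0.14 nm → 1.4 Å). Residues are addressed by the author
numbering of the deposited structure — the BTK kinase domain spans residues
389–658, and Thr474, Tyr551 etc. mean exactly those numbers — and are never
renumbered. Insertion codes are part of the residue key. Frames are
1-indexed, the R convention; metric tables carry both the frame index and,
when the trajectory has times, the time in ns. For alternate-location
records the highest-occupancy conformer is kept (first on ties), with a
warning.

The shipped region set (`btk_default_regions()`) encodes the BTK
sub-structures: global kinase domain 389–658, A-loop 539–559, its
hydrophobic C-terminal part 550–558 (carrying Tyr551), DFG motif 539–541,
P-loop 410–415, hinge 475–479, plus the single-residue anchors Leu518,
Asn526, Asp539, Tyr551. Other proteins are analysed by supplying a YAML
region config (`read_regions()`). "Backbone" means the `{N, CA, C, O}`
atom set — the common convention when no atom list is stated.

## Superposition-based observables

**Kabsch superposition.** `kabsch_superpose()` finds the proper rotation
and translation minimising the weighted RMSD between matched point sets,
via the SVD of the weighted covariance; when the optimal orthogonal map
would be a reflection, the smallest singular direction's sign is flipped.
Configurations of rank < 2 (collinear point sets) leave a rotational degree
of freedom undetermined and are rejected. The test suite checks the minimal
RMSD against an independently coded quaternion-eigenvalue solver to 1e-9 Å.

**RMSD series** superpose each frame's selection onto a reference before
measuring, so they report internal deformation, not rigid-body drift. The
reference is the first analysed frame by default — the simplest
reproducible convention when a plotted series does not name one — with the
ensemble mean available by flag. The value at the reference frame is 0.

**RMSF profiles** superpose every frame onto the ensemble mean structure
and recompute the mean once after realignment (a single refinement pass;
further iteration changes equilibrated ensembles by less than numerical
tolerance, which the planted-noise recovery below confirms at the 2–3%
level). The per-residue value is the root of the mean squared fluctuation
of the residue's selected atoms, so a Cα selection gives the conventional
Cα RMSF.

**Radius of gyration** is `sqrt(Σ w_i |r_i − r_c|² / Σ w_i)`, mass-weighted
over the backbone selection by default (uniform weights by flag), per
frame.

**The β6/β7–DFG angle** is the angle, in degrees within [0°, 180°], between
the line from Leu518 (β6) to Asn526 (β7) and the line from Leu518 to Asp539
in the DFG motif; a decrease means the DFG motif has closed toward the β
sheet. **The DFG↔ATP-site distance** is measured from the DFG centroid to
the midpoint of the P-loop and hinge centroids — the centre of the ATP
binding site. Literature descriptions of these "centre points" do not state
the atom set; the package defaults to unweighted Cα centroids (residues,
not atoms, are named in such definitions) and offers heavy-atom centroids
by flag.

## Solvent-accessible surface area

`sasa_frame()` implements the Shrake–Rupley construction: each atom's van
der Waals sphere is inflated by the probe radius (1.4 Å, a water molecule)
and covered with `n_points` quasi-uniform lattice points; the accessible
area is the exposed-point fraction times `4π(r+rp)²`. Three deliberate
choices:

- **Deterministic Fibonacci lattice**, not random points: identical inputs
  give bit-identical areas. The default `n_points = 960` leaves the
  two-sphere closed form (spherical cap) reproduced to ~0.1% and region
  sums converged to < 0.5% under point doubling.
- **Principal-axis canonicalisation** (`canonical = TRUE`): a finite fixed
  lattice cannot be exactly pose-invariant, so coordinates are rotated into
  the structure's principal-axis frame (signs fixed by third moments)
  before the lattice is applied. Areas are then invariant under rigid
  motions of the input to well below 1e-6 Å². The complementary
  monotonicity property — removing an occluder can only increase areas —
  holds exactly at a fixed lattice orientation (`canonical = FALSE`); the
  suite tests each property in its regime. Canonicalisation is degenerate
  for structures with symmetric inertia tensors (an isolated pair of
  atoms), where only the closed-form fixtures are meaningful anyway.
- **Neighbour search** uses a cell list with cells of twice the maximum
  inflated radius; a brute-force all-pairs mode exists as an oracle and
  gives *identical* areas for the same lattice, which the suite asserts.

Radii come from a Bondi-style element-keyed table (`default_vdw_radii()`),
overridable per call; hydrogens are excluded by default. The upstream
literature rarely states its radii set or point count, so these defaults
are package decisions, not reproductions. Per-residue SASA is the sum over
the residue's included atoms; region series sum the region's residues
against the full structure as occluder.

## Hydrogen bonds, salt bridges, occupancy

A hydrogen bond requires donor–acceptor distance < 3.5 Å and "the
donor–hydrogen–acceptor angle < 30°". That angle criterion is implemented
as the **deviation-from-linearity** convention: the angle between the D→H
and D→A vectors must be under the cutoff, the meaning used by the common
trajectory-analysis tools. A literal reading — the interior D–H–A angle
under 30° — would describe a hydrogen folded back against its donor, a
geometry essentially impossible for a real hydrogen bond; it is provided as
`angle_mode = "literal"` for comparison only. Hydrogens are assigned to the
nearest covalent N/O/S donor within 1.25 Å; structures without hydrogens
either raise a missing-hydrogen error or, by flag, fall back to
distance-only detection. Within-residue pairs and adjacent backbone
amide–carbonyl (i, i±1 N–O) pairs are excluded, and a frame's multiple
qualifying atom pairs between one residue pair collapse to a single
presence — the bond-survival semantics.

A salt bridge requires any basic-nitrogen/acidic-oxygen pair (Lys NZ, Arg
NE/NH1/NH2 vs Asp OD1/OD2, Glu OE1/OE2) closer than 4.0 Å; one record per
residue pair carries the minimum N–O distance. Histidine is excluded from
the basic set by default because its charge is protonation-dependent; a
flag includes ND1/NE2.

**Occupancy** is the percentage of frames in which the interaction is
present — per run when a grouping is given, with cross-run mean and s.d.
The detectors are validated against a brute-force all-pairs oracle
(exact agreement) and against planted Bernoulli timelines (frame-exact
agreement, occupancy inside the binomial 95% interval at 5000 frames for
formation probabilities 0.2–0.9).

## Statistics

Groups of runs are compared with the unpaired two-tailed Student's t-test
(pooled variance, `df = n_a + n_b − 2`), significance at p < 0.05. The
p-value is computed through the regularized incomplete beta function,
`p = I_{df/(df+t²)}(df/2, ½)`, and checked against an independent t-CDF
evaluation to 1e-10 across a (t, df) grid. The inference unit is the **run**
by default: each run contributes its time mean, so three independent
simulations per system give n = 3 per group. Frames are autocorrelated, not
independent; treating each frame as a replicate inflates n by orders of
magnitude, so `unit = "frame"` exists but stamps an explicit
pseudo-replication warning into the report. Zero pooled variance with equal
means yields t = 0, p = 1; with unequal means it is an error, not a
fabricated p. No multiple-testing correction is applied, matching the
single-comparison-per-panel design this pipeline serves.

## The synthetic benchmark

Cluster-scale MD (three 100 ns replicas per system) is not reproducible at
desk scale, so the package carries a generator of synthetic trajectories
with *planted, machine-readable truth*, and the validation suite tests the
analysis side against that truth rather than against re-simulation.

The toy peptide (`make_toy_topology()`) places backbone N/CA/C/O (plus
amide hydrogens, CB, and minimal polar side chains for Ser, Thr, Leu, Met,
Asp, Asn, Glu, Lys, Arg, Tyr) on a loose helical-tube trace: consecutive
residue origins are ~3.7 Å apart, as in a real chain, and the trace spans
all three dimensions. The 3-D trace matters: an extended straight chain is
nearly collinear, which leaves the Kabsch rotation about the chain axis
undetermined and badly biases RMSF estimates; on the helix the planted
amplitudes are recovered to within 2–3%.

Four orthogonal, composable plants cover the pipeline:

- **Fluctuations**: per-residue Gaussian displacements with chosen σ (Å per
  coordinate). The closed form `RMSF = σ√3` is the recovery target.
  Hydrogens ride their parent heavy atom's displacement so covalent
  geometry — and donor–hydrogen assignment — survives the noise.
- **Bond toggles**: per frame, a residue pair's planted atoms are placed in
  an on-geometry (collinear D–H⋯A at 2.9 Å; N–O at 3.2 Å for bridges) or an
  off-geometry (6.0 / 8.0 Å) by a Bernoulli draw; both geometries are
  asserted against the detection criteria at generation time, and the true
  timeline is returned. Bystander N/O/S atoms that noise pushes into the
  planted hydrogen's covalent shell are nudged clear, keeping the truth
  exact by construction.
- **Rigid motions**: uniform SO(3) rotations (normalised quaternions) plus
  random translations — the invariance fixture for every observable.
- **Angle series**: the third anchor atom is re-placed each frame so the
  vertex angle equals the requested value exactly, whatever noise the base
  carries.

**Study conditions.** The two benchmark ensembles
(`gen_condition_run()`, both on a BTK-numbered 172-residue domain,
389–560) encode the qualitative contrasts a gatekeeper mutation produces,
with three runs per condition mirroring a three-replica design:

| plant | WT-like | mutant-like |
|---|---|---|
| baseline σ (Å/coord) | 0.15 | 0.15 |
| A-loop σ (539–559) | 0.30 | 0.60 |
| C-term segment 550–559 | packed against chain | displaced 9 Å radially (exposed) |
| β6/β7–DFG angle (°, mean ± 1) | 82 | 78 |
| p(Ser543–Asp521 H-bond) | 0.48 | 0.15 |
| p(Gly541–Leu518 H-bond) | 0.15 | 0.85 |
| p(Asp539–Asn526 H-bond) | 0.15 | 0.55 |
| p(Arg544–Glu445 bridge) | 0.60 | 0.15 |

The bond probabilities sit at the occupancy levels the BTK literature
reports for these four interactions (a firm ~60% bridge and ~48% bond in
the wild type collapsing below 20% in the mutant; the two DFG-side bonds
strengthening from below 20% to above 50–85%); the ~4° angle contrast
matches the reported DFG closure. These are *planted* values — recovering
them demonstrates that the analysis pipeline measures what it claims on
data with known answers, not that any physical simulation was reproduced.
The synthetic dynamics have no force field, no solvent, no autocorrelation
and no coupling between observables; passing tests therefore validate the
estimators and detectors, and say nothing about conformational sampling of
real proteins.

**Problem sizes.** The validation suite uses 2000 frames and 150 residues
for fluctuation recovery (sampling error and superposition leakage both
comfortably under the 3% target — the fit absorbs about `6/(3N)` of the
variance and leaks rotational noise onto low-σ residues, so small systems
bias the profile), 5000 frames for occupancy recovery (binomial 95%
half-width ~1.4% at p = 0.6), and 3 × 120 frames per condition for the
end-to-end comparison; the region SASA series there uses a 240-point
lattice, whose discretisation error is far below the planted contrast. All
generators are bit-reproducible from their seeds.

## Numerical and degenerate-input policy

Superposition requires ≥ 3 non-collinear points. Angle arms of zero length
are degenerate-geometry errors. Empty selections name the offending range.
Single-frame trajectories cannot yield an RMSF. DCD reading auto-detects
byte order from the header framing and reports recovered frame counts on
truncation; writing uses 32-bit floats (round trip ≤ 1e-5 Å). Metric TSVs
print at 6 significant digits, making identical analyses byte-identical on
disk. The t-test's run-level unit, the 0.05 threshold, and all detection
cutoffs are configurable but default to the field's standard values.

## Known limitations

- The frame-saving interval of a trajectory is often unknown; tables treat
  the frame index as primary and time as optional metadata.
- Occupancies depend on which window (equilibration vs production) is
  analysed; `cmd_compute()` takes an explicit frame window and leaves the
  choice to the user.
- SASA canonicalisation assumes a generic inertia tensor; symmetric
  arrangements fall back to the laboratory frame.
- No PSF/PRMTOP topologies, no XTC/TRR formats, no secondary-structure
  assignment, no PCA/cross-correlation analyses, no energetic H-bond
  scoring, and no relative-SASA normalisation — these are out of scope.
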