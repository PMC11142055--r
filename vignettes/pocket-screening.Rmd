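---
title: "Methods: pocket detection, surface comparison and the selectivity screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket detection, surface comparison and the selectivity screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pocketscreen` implements the computational stages of a structure-first
selectivity screen: find druggable surface pockets on protein structures,
compare pocket surfaces by shape and chemistry, filter and rank compound
libraries, and score screening outcomes by the efficacy ratio against bone
marrow. This vignette is the package's account of each method, the
parameters that matter, the design choices made where the design was
genuinely open, and what the test suite does and does not establish.

## Pocket detection

### Model

Atoms are balls at the crystallographic coordinates with Bondi van der
Waals radii (`bondi_radii()`; unlisted elements default to 1.50 Å with a
warning). Pockets are found on the *unweighted* Delaunay triangulation of
the atom centers (`delaunay3d()`, incremental Bowyer–Watson):

* **Emptiness.** A tetrahedron admits the solvent probe (radius `probe_radius`,
  default 1.4 Å, water) when its circumsphere radius minus the mean radius
  of its four member atoms is at least the probe radius.
* **Wide faces.** A triangular face is passable when its circumcircle
  radius minus the mean radius of its three atoms exceeds the probe
  radius. Flow, basin merging, and mouth classification all respect this:
  a probe cannot move through a face it does not fit through.
* **Discrete flow.** Each empty tetrahedron flows across the face its
  circumcenter lies beyond — toward locally larger empty space. Flow that
  would cross a narrow face, or enter a non-empty tetrahedron, pools
  (sink); flow through a wide hull face escapes to bulk solvent.
  Pockets are the probe-connected components of empty tetrahedra whose
  flow drains to interior sinks. Components that cannot hold even one
  probe sphere (void volume < (4/3)πr_p³) are discarded as slivers.
* **Mouths.** Boundary faces of a pocket that open, through a wide face,
  onto bulk solvent or through the convex hull are mouth faces; their
  edge-connected components are the mouths. An interior void has no mouth.

The unweighted construction with the radius-corrected emptiness test is a
deliberate approximation to the weighted alpha-complex used by
full-resolution pocket servers: it is simpler, fully testable at desk
scale, and yields the same qualitative pockets on the fixture family. Flat
surface slivers — which pass a pure circumsphere test spuriously — are
neutralised by the wide-face rule plus the minimum-volume cut rather than
by a weighted triangulation.

### Measurements and conventions

* **Area** is the summed area of wall triangles on the *atom-center* mesh
  (no molecular-surface correction). The druggability threshold of 500 Å²
  applies to this convention and is configurable in `filter_druggable()`.
* **Void volume** is the solvent-accessible void: the volume of the
  pocket's empty tetrahedra lying farther than (r_vdw + probe) from every
  atom, i.e. where a probe *center* can sit. It is estimated by Monte
  Carlo in barycentric coordinates (64 samples per tetrahedron by
  default) under a fixed internal seed keyed to tetrahedron order, which
  makes the estimate exactly equivariant under rigid motion of the input —
  the rotation-invariance test asserts agreement to 1e-6 relative.
* **Polar residues** are counted as distinct residues contributing atoms
  to the pocket whose class is polar (SER, THR, ASN, GLN, TYR, CYS, HIS,
  TRP) or charged (ASP, GLU, LYS, ARG). The druggability criterion "at
  least two polar residues" counts polar ∪ charged, since both can anchor
  hydrogen bonds to a ligand; the sets are configurable in
  `residue_polarity_sets()` because the published criterion does not
  define them.
* **Degenerate input** (coplanar/collinear centers) raises a geometry
  error. The triangulation expects generic positions; the synthetic
  shell generator adds ~0.1 Å seeded positional noise precisely so that
  no four points are exactly cospherical.

An independent oracle, `grid_reachability()`, classifies space by dense
grid flood fill (0.25 Å spacing) from outside the structure; on closed
cavities the unreached free cells agree with the tetrahedral void to
Jaccard ≥ 0.95 (in practice ≈ 1.0 on the fixtures).

## Surface comparison

* **Shape signature.** Points are sampled uniformly by area on the
  boundary triangles (512 points), paired at random (4096 pairs), and the
  pair distances histogrammed into 64 equal-width bins. The signature
  keeps the raw distances, so `ks_compare()` computes the exact
  two-sample D over the union of sample points; the p value uses the
  asymptotic two-sample formula with effective size n₁n₂/(n₁+n₂) and the
  Stephens small-sample correction. Tests verify D against direct ECDF
  enumeration and against `stats::ks.test` as an independent oracle.
* **Superposition.** `superpose()` is the SVD (Kabsch) least-squares
  solution with reflection corrected to det +1, over a user- or
  package-derived correspondence of same-labeled points. cRMSD is the
  residual coordinate RMSD; oRMSD is the root mean square angle between
  the target's orientation vectors and the rotated orientations of the
  moving surface. The orientation vector of a residue is the unit vector
  from its alpha-carbon to its side-chain heavy-atom centroid (synthetic
  pseudo-residues and glycine fall back to the outward vector from the
  structure centroid); this definition is a package choice — orientation
  RMSD is named but not defined in the source methodology.
* **Correspondence for unaligned pockets** defaults to mutual nearest
  neighbors among same-labeled points after centroid superposition
  (`derive_correspondence()`); it is one of several plausible schemes and
  is deliberately replaceable.
* **Random-alignment null.** `alignment_null_pvalue()` rotates the moving
  surface by uniform quaternion-sampled rotations, re-derives the
  mutual-NN correspondence each time, and reports the permutation-style
  p = (1 + #{null ≤ observed})/(n_random + 1), so p is never 0 and a
  perfect self-alignment gives 1/(n_random+1).
* **Volume Tanimoto.** Pocket volumes are voxelized (0.5 Å default) on a
  common grid after applying the alignment to the second pocket; the grid
  is offset by half a cell so voxel centers never sit exactly on
  axis-aligned volume boundaries (this removes a one-layer double-count
  that otherwise biases the half-offset-cube oracle from 1/3 to 0.355).
* **Composite score.** The published pipeline combines these statistics
  into a composite score whose exact form and weights are unpublished;
  only monotonicity is inferable. The package default is the flagged,
  configurable linear rule
  `w₁(1−D) + w₂(1−p_align) + w₃·Tanimoto` with equal weights — monotone
  non-decreasing in every similarity component, 0 for totally dissimilar
  parts, and maximal for self-comparison on the fixture suite.

## Compound property filter

Descriptor conventions follow Lipinski-style filtering, since the
published filter parenthesizes donor/acceptor limits next to TPSA:
HBD = count of N–H and O–H hydrogens (computed on the explicit-hydrogen
graph), HBA = count of N and O atoms. MW and TPSA (Ertl fragment scheme)
come from OpenBabel via ChemmineR/ChemmineOB, which also does all SMILES
parsing. Bounds: MW inclusive on [160, 480] g/mol ("between 160–480"),
TPSA/HBD/HBA strict (< 140 Å², < 5, < 10), mirroring the wording of the
filter; a molecule with TPSA exactly 140.0 fails. Every failing criterion
is recorded in `fail_reasons`, which is empty exactly when the compound
passes.

## Screening funnel

The funnel architecture — not any physics engine — is the contribution
implemented here. Scorers are pluggable (`make_scorer`): a name, a
deterministic flag, an ordinal `cost_tier`, and a function returning a
real score where lower is better. Docking and free-energy engines are out
of scope and represented only by this contract; the built-in
`toy_scorer()` (size and polarity complementarity with a documented
closed form and a constructed zero) stands in for them in tests and
examples. Open design points resolved as package decisions: ranks from
multiple scorers in a stage aggregate by mean rank by default (best rank
available); ties break lexically on compound id for full determinism; the
per-stage K values are caller-supplied since no canonical values are
published. Provenance records the last stage each compound survived;
tests assert funnel/exhaustive-scoring equivalence when nothing is culled
and top-1 preservation under monotone-consistent stage scorers.

## Selectivity screen

* **Activity threshold.** Strictly `ratio < 0.5`. The 5.7 µM table's
  0.49 entry counts as active — that is what makes Dxr2-017's relative
  activity 75% there, and the tests pin this.
* **Rounding.** Relative activities round half away from zero (62.5 → 63,
  matching the printed tables; R's own `round()` is half-even). Printed
  ratios are 2-decimal; parity statistics are computed on them as given.
* **Pooled site statistics.** A site's pooled mean/SEM are computed over
  *all* sub-threshold ratios of its active compounds (validated against
  the printed per-site means of 0.06, 0.15 and 0.13); per-compound-mean
  pooling is available as an option. SEM uses the n−1 sample convention
  and degenerates to 0 for a single value (matching the printed "0"
  entries). SEMs are reported but not asserted against the printed ones:
  the published SEMs (0.022, 0.091) were evidently computed on unrounded
  raw assay data that is not available, and 2-decimal inputs give 0.021
  and 0.083.
* **Known inconsistencies in the printed tables.** Two printed
  relative-activity entries do not reproduce from the printed ratios
  themselves: FolC1-020 at 40 µM prints 73 where 5 of 7 tested lines are
  below 0.5 (= 71; no k/7 or k/8 rounds to 73), and FolC2-001 at 5.7 µM
  prints 13 where none of its 8 printed ratios is below 0.5. The bundled
  fixtures keep the printed ratios verbatim (including the "HT116"
  cell-line spelling and "-" for untested entries, checksum-pinned); the
  package reports the recomputed values and documents the discrepancy
  rather than silently matching or correcting either number.
* **Marrow recovery rule.** The flags derive from day-8 percent of
  control alone (>10% inhibition: day8 < 90; >30%: day8 < 70). The
  day-14 call — recovered when day14 ≥ 90, partial when
  day8 ≤ day14 < 90, none otherwise — is a package convention chosen to
  express the reported 4 recovered / 1 partial / 1 none outcome among the
  6 flagged compounds; both cutoffs are arguments.
* **IC50.** Log-linear interpolation between the two measured points
  bracketing 50% of control. Extrapolation is refused (`estimable =
  FALSE`) rather than guessed; an exact 50% measurement is returned
  as-is. On dense zero-noise logistic curves the planted value is
  recovered within 10% (within 0.1% in practice).

## Synthetic-data generators

* **Cavity structures** (`make_cavity_structure`). Pseudo-atoms on a
  Fibonacci sphere lattice, with zero, one, or two antipodal circular
  openings, residue names cycling through a configurable lining (default
  SER, SER, LEU, giving a controllably polar pocket), and seeded ±0.12 Å
  positional noise (degeneracy breaking, see above). Atom centers sit at
  `interior_radius + r_vdw + probe`, so the accessible void is
  analytically a ball of the requested interior radius — the volume
  oracle is exact by construction. Defaults (interior 6 Å, 2.0–2.2 Å
  spacing, ≈ 200 atoms) keep single detections around a second.
* **Compound libraries** (`make_compound_library`). Every compound is
  generated together with the verdict the filter must reach: in-range
  alkanes/alcohols, sub-160 alkanes (ethanol always included), supra-480
  alkanes, oligoglycines (TPSA ≥ 140), polyols (≥ 5 donors), methyl-capped
  polyethers (≥ 10 acceptors). The class fractions (40% pass / 60%
  spread over the failure modes) exercise every boundary.
* **Colony tables** (`make_colony_table`). Percent-of-control values are
  drawn from four-parameter Hill (logistic) means — the natural family
  for a monotone sigmoidal dose response, and the one the IC50 contract
  assumes — with truncated Gaussian noise (never below 0; default SD 5
  percentage points) and duplicate wells (N = 2 replicates, the assay
  design). The planted selective site's compounds get sub-micromolar
  cancer potency with inert marrow response; non-selective compounds are
  either inert everywhere or *equitoxic* with moderate (≈ 50%) maximal
  inhibition on both compartments, so their ratios concentrate near 1
  with modest variance. Equitoxic compounds are given moderate rather
  than near-complete inhibition deliberately: ratios of two small noisy
  percentages would be noise-dominated and would plant false "actives"
  that no real equitoxic compound profile implies. Marrow day-14 values
  apply a per-compound recovery multiplier.

### What the simulations do and do not show

The generators emulate the *statistical* structure the screen assumes —
monotone dose response, replicate noise, site-segregated selectivity,
marrow recovery — on geometrically idealised structures. They do not
emulate real crystallographic pockets (side-chain geometry, partial
occupancy, heteroatom chemistry), correlated assay noise or plate/batch
effects, or real docking score landscapes. Passing tests therefore
establish the correctness of the algorithms and statistics, not the
biological performance of the screen on new proteins.

## Problem sizes and budgets

The test and acceptance workloads use ≈ 200-atom shells (Delaunay ≈ 1 s
each in pure R), 0.25 Å oracle grids (≈ 100³ cells), 250-compound
libraries, 100-seed simulation ensembles, and 99–999 random alignments —
sizes chosen so the full suite runs in about two minutes on one core
while every assertion still has headroom against its tolerance.

## Known limitations

* Unweighted Delaunay with mean-radius corrections approximates, but is
  not, the weighted alpha complex; heavily mixed-radius structures shift
  pocket boundaries slightly.
* Pocket void volume includes the mouth's cap region up to the flow
  separatrix; on the open test cavity this overshoots the interior ball
  by ≈ 5–10% (inside the stated ±20% oracle band).
* Pure-R Bowyer–Watson is comfortable to ~1000 atoms; full protein
  structures should be cropped to the region of interest first.
* `ic50_estimate` interpolates; it does not fit a parametric curve and
  will not average out noisy replicates — feed it replicate means.
* mmCIF, assemblies/symmetry expansion and nucleic-acid chains are out of
  scope for the PDB reader.
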