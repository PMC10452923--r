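---
title: "Analysing short-peptide aggregation on metal surfaces with surfagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing short-peptide aggregation on metal surfaces with surfagg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfagg)
```

## The scientific problem

Short amyloidogenic peptides such as the amyloid-beta fragment
Aβ(16–22), sequence KLVFFAE, aggregate readily in solution into compact,
β-strand-rich oligomers — the early species on the route to amyloid
fibrils. Solid–liquid interfaces can change this behaviour qualitatively:
on a gold (111) surface the phenylalanine side chains adhere strongly to
the metal, peptides lie flat, and aggregates grow as extended
two-dimensional monolayers of bent, surface-moulded conformers instead of
compact β-sheet nuclei. Distinguishing these two regimes from
molecular-dynamics trajectories requires a small but specific set of
observables, which this package implements as a tested, reusable pipeline:

* **oligomer detection** — two peptides belong to the same cluster when
  any two heavy (non-hydrogen) atoms, one from each, are strictly closer
  than 4 Å (0.4 nm) under the minimum-image convention; oligomers are the
  connected components of this graph (single linkage). From the per-frame
  partition come the largest-oligomer time series and oligomer-size
  histograms.
* **shape** — the gyration tensor of each oligomer, i.e. the
  mass-weighted second-moment tensor about the centre of mass. We report
  the square roots of its sorted eigenvalues, `Gmax >= Gmid >= Gmin`, in
  nm, so values are commensurate with molecular lengths, together with
  `Rg` (so `Gmax^2 + Gmid^2 + Gmin^2 = Rg^2`). A flat monolayer shows
  `Gmin` near the single-molecule value; a compact aggregate does not.
* **residue contact and hydrogen-bond maps** — intermolecular
  residue–residue contact frequencies under the same heavy-atom
  criterion, and geometric hydrogen-bond counts (donor–acceptor
  ≤ 3.5 Å, hydrogen–donor–acceptor angle ≤ 30°). An antiparallel β-sheet
  concentrates H-bonds on the anti-diagonal of the residue–residue map.
* **conformational classification** — the distance RMSD (DRMSD) between
  a peptide's intramolecular Cα–Cα distances and a reference set,

  $$\mathrm{DRMSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}
      \left(r_i - r_i^{\mathrm{ref}}\right)^2},
      \qquad N = \tbinom{R}{2} = 21 \text{ for } R = 7,$$

  computed in nm and reported in Å. Being built from internal distances
  only it needs no superposition and is invariant under rigid motions
  *and reflection* — mirror conformers are indistinguishable, a property
  of the metric that we document rather than correct. Ramachandran
  (φ, ψ) densities with quadrant occupancies complement it: the
  upper-left quadrant (φ < 0, ψ > 0) holds β-strand conformations, the
  lower-left α-helical ones.
* **surface geometry** — an fcc(111) slab builder (nearest-neighbour
  spacing $a/\sqrt2$, interlayer spacing $a/\sqrt3$, ABC stacking),
  areal peptide densities $n/(N_A L_x L_y)$, residue/peptide z-profiles
  above the top atomic layer, and a monolayer/multilayer/detached
  classification of adsorbed aggregates.

## Conventions and tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| contact cutoff | 0.4 | nm | heavy-atom contact criterion, strict `<` |
| analysis window | 100 | ns | trailing window for all averaged observables |
| DRMSD histogram bin | 0.1 | Å | `drmsd_histograms()` |
| Ramachandran bin | 5 | ° | `ramachandran()` |
| H-bond distance / angle | 0.35 nm / 30° | | geometric criterion |
| surface contact height | 0.5 | nm | above top-layer z |
| adsorption persistence | 0.5 | fraction | of window frames in contact |
| lattice parameter | 4.14 | Å | gold; slab builder |

Internal length unit is nm throughout; the single conversion point is
I/O (PDB files are Å). The cutoff comparison is strict (`< 0.4 nm`) so
that boundary behaviour is deterministic; an engineered pair at exactly
0.40 nm is *not* a contact. Periodicity is all-axes for solution boxes
and x/y-only for surface systems — the slab plus vacuum makes z-wrapping
physically meaningless for peptide–surface distances, so we impose this
even when the file declares a z box length. The trailing window falls
back to the trailing 20 % of frames (with a warning) when a trajectory is
shorter than the requested window, so short synthetic runs work
unchanged.

Two conventions are deliberately exposed as switches because the field
uses both:

* the oligomer-size histogram is **peptide-weighted** by default,
  `P(s) = s·count(s) / (Nmol · frames)` — the probability that a randomly
  chosen peptide sits in an s-mer — with cluster-counting available via
  `weighting = "cluster"`;
* the gyration tensor is mass-weighted by default, with an unweighted
  (geometric) variant by flag, and both the principal radii (nm) and the
  raw eigenvalues (nm²) are emitted.

Peptide copies are identified by chain/segment ID when present, else by
residue-numbering restarts (GRO files often carry no chain IDs); peptide
indices are 1-based in the R API. Supported inputs are PDB (single- and
multi-model), GRO and binary DCD; XTC is not read — no R-side reader
exists and DCD or multi-model PDB cover the same role.

## Reference conformations

DRMSD needs reference distance sets. The package takes references as
input files (PDB, or a one-header-line plain-text vector of the 21
distances in nm; see `inst/extdata/`) and also ships two *constructed*
canonical references built by its own generator:

* **fibril-like** — an ideal extended β-strand, φ = −139°, ψ = +135°,
  standing in for a fibril-state conformation;
* **surface-like** — a flat-lying bent conformation with both
  phenylalanine pseudo-side-chains coplanar and pointing down.

These are synthetic stand-ins, not experimental structures; every
shipped-reference result is to be read as "distance from the ideal
β-strand / from the constructed flat conformer".

## The synthetic-data generator

All fixtures are generated in code; no MD engine and no downloads are
needed. Two generators cover complementary needs.

**Constructive planted configurations** (`plant_configuration()`).
Peptides are built at backbone-plus-pseudo-side-chain resolution (N, H,
Cα, Cβ, C, O per residue — six atoms, of which five are heavy) from
planted dihedrals by natural-extension (NeRF) chaining with ideal bond
lengths and angles. This resolution is sufficient for every analysis in
the package (heavy-atom contacts, Cα DRMSD, φ/ψ, N–H/C=O hydrogen-bond
geometry) while keeping fixtures tiny. Cluster members are placed
side-by-side so that the realised contact graph at 0.4 nm *exactly*
equals the planted partition — the placement scan targets a closest
approach between 0.30 and 0.37 nm and prefers positions with at least
five heavy-atom pairs below 0.37 nm, so that small coordinate noise
cannot sever a planted contact — and the construction is verified
against `partition_frame()` before emission. Adsorbed peptides sit with
their phenylalanine pseudo-atoms 0.3 nm above the top slab layer,
stacked (multilayer) members 0.3–0.4 nm above the adsorbed layer, and
detached peptides 2.5 nm up. Gaussian coordinate noise of stated
amplitude is added last. Planted dihedral sets keep at least 30° margin
from Ramachandran quadrant boundaries, so that quadrant-occupancy truths
remain well-posed under noise (0.02 nm coordinate noise already
propagates to roughly 15–20° of dihedral jitter over the short backbone
lever arms; a planted angle near a boundary would make "recovery"
measure boundary flicker instead).

**Langevin bead-chain aggregator** (`langevin_aggregate()`). One bead
per residue, bonds at the 0.38 nm Cα virtual-bond length, a weak 1–3
term for semi-flexibility, soft-core repulsion, and Gaussian-well pair
attractions by residue class: hydrophobic–hydrophobic (L/V/F/A)
attractive, K⁺–E⁻ attractive, like-charge repulsive. With a slab, PHE
beads feel an attractive Gaussian wall 0.3 nm above the surface. The
update is overdamped (position) Langevin,
`x += F·dt/γ + sqrt(2·kT·dt/γ)·ξ`, deterministic given the seed — chosen
over velocity Verlet plus thermostat because it is simpler and adequate
for generating aggregation-like statistics. It makes no claim to
approximate any particular force field; it exists so that kinetics-shaped
inputs (aggregation events at unknown frames, adsorption ordering with
F beads low) exercise the pipeline. Defaults sit in a moderate regime;
the strong-adhesion demonstrations in the tests use a deeper, wider
hydrophobic well (25 kJ/mol, 0.15 nm) in a small box, chosen at design
time as the clearly-aggregating regime.

What the generators do **not** emulate: water and explicit electrostatics,
side-chain chemistry beyond one pseudo-atom, polarisable gold, realistic
kinetics or free energies. Passing tests therefore demonstrate the
*correctness of the analysis pipeline* on data with known ground truth,
not the physics of any particular peptide–surface system.

## Numerical choices

* Clusters are made whole across periodic boundaries before the gyration
  tensor is computed: breadth-first over the contact graph from the
  lowest-index member, shifting each newly reached peptide by the image
  vector of its closest contact pair. Clusters spanning a full periodic
  axis cannot be unwrapped consistently and are returned flagged rather
  than silently wrapped.
* Component sorting is deterministic: size descending, ties by smallest
  member index; the unwrap anchor is the lowest peptide index.
* Torsions use the standard atan2 four-atom formula with the sign
  convention of the common structural-biology tools (cross-checked
  against `bio3d::torsion.xyz` in the tests); angles live in
  (−180°, 180°], quadrant assignment puts φ = 0 on the right and ψ = 0
  on the lower half.
* Histograms: DRMSD histograms are densities (integrate to 1);
  Ramachandran densities are probability masses (sum to 1).
* Degenerate inputs error loudly: empty trajectories, non-monotonic
  times, mismatched atom counts, mixed residue counts across peptides
  (with the offending peptide named), H-bond analysis on hydrogen-free
  topologies (pointing to the heavy-atom contact map instead), windows
  longer than the trajectory (suggesting an explicit override).

## Problem sizes used in the tests

The test-suite and the acceptance script run entirely on synthetic
systems of 1–8 peptides (42 atoms each at six-atom resolution, or 7
beads in the Langevin model), trajectories of 1–11 frames for planted
configurations and a few thousand Langevin steps for kinetics, 200+
random frames for the clustering-oracle equivalence and 50 seeded
specifications for planted-truth recovery. These sizes were chosen so
the whole suite is a desk-scale computation; every quantity is
recomputed from scratch at run time.

## Known limitations

* DRMSD cannot distinguish mirror images; a planted left-handed
  conformer scores 0 against its right-handed reference.
* The monolayer/multilayer label is a global summary (all/none/mixed
  adsorption); per-cluster labels can be derived from the per-peptide
  flags and the partition if needed.
* The quadrant-occupancy recovery at 0.02 nm noise hovers near 95 %:
  dihedral noise amplification over short lever arms is the limiting
  factor, not the estimator.
* No DSSP-style secondary-structure assignment, no salt-bridge-specific
  detector, no kinetic modelling, and no free-energy estimates — the
  observables above are the package's scope.
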