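# surfagg

Post-processing for molecular-dynamics trajectories of short
amyloidogenic peptides — the amyloid-beta fragment Aβ(16–22), sequence
KLVFFAE, is the motivating system — aggregating either in bulk solution
or on an fcc(111) gold surface. The package is aimed at simulators who
need the standard observable set for telling compact, β-strand-rich
solution oligomers apart from flat, surface-moulded monolayer
aggregates, without re-writing one-off analysis scripts per project.

## What it computes

* **Oligomers** — single-linkage clusters under the heavy-atom contact
  criterion (two peptides are connected when any two non-hydrogen atoms
  are strictly closer than 4 Å, minimum-image); largest-oligomer time
  series and oligomer-size histograms
  `P(s) = s·count(s)/(Nmol·frames)` over a trailing window.
* **Shape** — gyration-tensor spectra per oligomer: principal radii
  `Gmax ≥ Gmid ≥ Gmin` (nm, square roots of the eigenvalues of the
  mass-weighted second-moment tensor), with
  `Gmax² + Gmid² + Gmin² = Rg²`.
* **Maps** — intermolecular residue–residue contact frequencies and
  geometric hydrogen-bond maps (donor–acceptor ≤ 3.5 Å, H–donor–acceptor
  angle ≤ 30°).
* **Conformation** — distance RMSD against reference conformations,

      DRMSD = sqrt( (1/N) Σᵢ (rᵢ − rᵢ_ref)² ),   N = R(R−1)/2,

  over all intramolecular Cα–Cα pairs (21 for a 7-residue peptide),
  reported in Å; plus Ramachandran (φ, ψ) densities with quadrant
  occupancies.
* **Surface** — fcc(111) slab builder (nearest-neighbour spacing a/√2),
  areal densities n/(N_A·Lx·Ly), residue/peptide heights above the top
  atomic layer, and monolayer / multilayer / detached classification.
* **Synthetic data** — a constructive generator planting oligomer
  partitions, conformations and adsorption states with known ground
  truth, and a coarse-grained overdamped-Langevin bead-chain aggregator,
  so the full pipeline runs and is testable with no MD engine.

Inputs: PDB (single- and multi-model), GRO, binary DCD. Outputs: CSV
tables plus a JSON run manifest.

## Worked example

Plant a four-peptide monolayer of flat-lying, surface-bent conformers on
a gold-like surface, with 0.02 nm coordinate noise, and analyse it:

```r
library(surfagg)

mono <- plant_configuration(synthetic_spec(
  4, partitions = list(list(1:4)), conformations = "surface-bent",
  adsorbed = TRUE, slab = TRUE, n_frames = 5, noise = 0.02, seed = 11))

partition_frame(mono$traj, 5)
#> Oligomer partition at t = 400 ps: {1,2,3,4}

gyration_spectrum(mono$traj, 5, 1:4)
#> Gyration spectrum (t = 400 ps, 4 peptide(s)): Gmax 1.189  Gmid 0.509  Gmin 0.110  Rg 1.298 nm

classify_adsorption(mono$traj)$label
#> [1] "monolayer"

dh <- drmsd_histograms(mono$traj, list(fibril = reference_fibril(),
                                       surface = reference_surface()))
mean(dh$fibril$series$drmsd);  mean(dh$surface$series$drmsd)
#> [1] 2.59   # far from the ideal beta-strand reference (Angstrom)
#> [1] 0.26   # close to the flat surface-bent reference

ramachandran(mono$traj)
#> Ramachandran density (20 angle pairs, 5 deg bins). Quadrant occupancy:
#>  upper_left  lower_left upper_right lower_right
#>        0.85        0.15        0.00        0.00

surface_density(4, 5.860, 6.090)
#> [1] 1.86e-07   # mol m^-2
```

Read as a whole: the four peptides form one aggregate (a single 4-mer
partition), every member is in surface contact (`monolayer`), the
aggregate is flat (`Gmin` 0.11 nm, an order of magnitude below `Gmax`),
and the per-peptide conformations sit on the surface-like reference
(mean DRMSD 0.26 Å) rather than the fibril-like one (2.59 Å) — the
signature that distinguishes surface aggregation from solution
aggregation. The full pipeline over a trajectory, writing
`largest_oligomer.csv`, `size_histogram.csv`, `gyration.csv`,
`contact_map.csv`, `hbond_map.csv`, `drmsd_hist_*.csv`,
`ramachandran*.csv`, `z_profile.csv`, `adsorption.csv` and
`manifest.json`, is

```r
run_pipeline(run_config(trajectory = mono$traj, out_dir = "run1"))
```

and `compare_runs(c("run1", "run2"))` tabulates DRMSD peaks, the
fibril-likeness mass below 1 Å, quadrant occupancies and mean gyration
spectra side by side. A thin command-line wrapper lives at
`inst/cli/surfagg.R` (`run`, `synth`, `compare` subcommands). The
methods vignette (`vignettes/peptide-surface-aggregation.Rmd`) documents
conventions, parameters and limitations.

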