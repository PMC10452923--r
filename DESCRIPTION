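Package: surfagg
Title: Analysis of Short-Peptide Aggregation on Metal Surfaces from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing pipeline for molecular-dynamics trajectories of
    systems containing multiple copies of a short amyloidogenic peptide
    (e.g. the amyloid-beta fragment KLVFFAE), optionally adsorbed on an
    fcc(111) gold slab. Detects oligomers per frame by single-linkage
    clustering under a heavy-atom contact criterion, computes largest-oligomer
    time series and peptide-weighted oligomer-size histograms, gyration-tensor
    shape spectra, intermolecular residue-residue contact and hydrogen-bond
    maps, distance-RMSD conformational classification against fibril-like and
    surface-like references, Ramachandran densities, surface z-profiles and
    monolayer/multilayer adsorption labels. Ships a synthetic-trajectory
    generator (constructive planted configurations and a coarse-grained
    overdamped Langevin bead-chain aggregator) so the whole pipeline is
    exercisable without any MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
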