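square_traj <- function() {
  atoms <- data.frame(name = "CA", element = "C", resname = "ALA",
                      resid = 1:4, peptide = 1L, stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  xyz <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  trajectory(sys, xyz, 0, box_spec(c(50, 50, 50), c(FALSE, FALSE, FALSE)))
}

test_that("gyration spectrum reproduces analytic point configurations", {
  g <- gyration_spectrum(square_traj(), 1, 1, mass_weighted = FALSE)
  expect_equal(c(g$gmax, g$gmid, g$gmin), c(1, 1, 0), tolerance = 1e-12)
  expect_equal(g$rg, sqrt(2), tolerance = 1e-12)

  atoms <- data.frame(name = "CA", element = "C", resname = "ALA",
                      resid = 1:3, peptide = 1L, stringsAsFactors = FALSE)
  tr <- trajectory(molecular_system(atoms),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0,
                   box_spec(c(50, 50, 50), c(FALSE, FALSE, FALSE)))
  g2 <- gyration_spectrum(tr, 1, 1, mass_weighted = FALSE)
  expect_equal(g2$gmax, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(c(g2$gmid, g2$gmin), c(0, 0), tolerance = 1e-12)
})

test_that("the spectrum is invariant under rigid motions and satisfies the Rg identity", {
  set.seed(21)
  pc <- plant_configuration(synthetic_spec(3, partitions = list(list(1:3)),
                                           noise = 0.02, seed = 6))
  base <- gyration_spectrum(pc$traj, 1, 1:3)
  expect_equal(base$gmax^2 + base$gmid^2 + base$gmin^2, base$rg^2,
               tolerance = 1e-10)
  for (k in 1:20) {
    Rot <- random_rotation()
    shift <- runif(3, -3, 3)
    coords <- pc$traj$coords
    coords[, , 1] <- sweep(coords[, , 1] %*% t(Rot), 2, shift, "+")
    trR <- trajectory(pc$traj$system, coords, pc$traj$times,
                      box_spec(c(100, 100, 100), c(FALSE, FALSE, FALSE)))
    gR <- gyration_spectrum(trR, 1, 1:3)
    expect_equal(c(gR$gmax, gR$gmid, gR$gmin),
                 c(base$gmax, base$gmid, base$gmin), tolerance = 1e-10)
  }
})

test_that("eigenvalue sum equals Rg^2 on random clusters", {
  set.seed(22)
  for (k in 1:100) {
    n <- sample(2:4, 1)
    coords <- lapply(seq_len(n), function(i)
      matrix(rnorm(12, sd = 0.5), 4) + i * 0.3)
    tr <- bead_traj(coords, resnames = c("LYS", "LEU", "VAL", "PHE"))
    g <- gyration_spectrum(tr, 1, seq_len(n))
    expect_equal(sum(g$eigenvalues), g$rg^2, tolerance = 1e-10)
    expect_true(g$gmax >= g$gmid && g$gmid >= g$gmin && g$gmin >= 0)
  }
})

test_that("duplicating every atom leaves the spectrum unchanged (mass normalisation)", {
  pc <- plant_configuration(synthetic_spec(2, partitions = list(list(1:2)),
                                           noise = 0, seed = 7))
  g1 <- gyration_spectrum(pc$traj, 1, 1:2)
  # duplicate by doubling every atom in place
  at <- pc$traj$system$atoms
  idx <- rep(seq_len(nrow(at)), each = 2)
  at2 <- at[idx, c("name", "element", "resname", "resid", "peptide",
                   "chain", "mass")]
  rownames(at2) <- NULL
  sys2 <- molecular_system(at2)
  tr2 <- trajectory(sys2, pc$traj$coords[idx, , 1, drop = FALSE],
                    pc$traj$times, pc$traj$box[[1]])
  g2 <- gyration_spectrum(tr2, 1, 1:2)
  expect_equal(c(g2$gmax, g2$gmid, g2$gmin), c(g1$gmax, g1$gmid, g1$gmin),
               tolerance = 1e-10)
})

test_that("clusters split by the periodic boundary are made whole before the tensor", {
  # two bead chains in contact near the box edge: one copy wrapped
  p1 <- cbind(c(0.1, 0.45), 0.5, 0.5)
  p2 <- cbind(c(9.85, 9.5), 0.5, 0.5)   # min-image distance 0.1-9.85 = 0.25
  tr <- bead_traj(list(p1, p2), box_len = c(10, 10, 10),
                  resnames = c("LYS", "GLU"))
  g <- gyration_spectrum(tr, 1, 1:2)
  expect_false(g$flagged)
  # unwrapped equivalent
  p2u <- cbind(c(-0.15, -0.5), 0.5, 0.5)
  tru <- bead_traj(list(p1, p2u), box_len = c(10, 10, 10),
                   resnames = c("LYS", "GLU"))
  gu <- gyration_spectrum(tru, 1, 1:2)
  expect_equal(c(g$gmax, g$gmid, g$gmin), c(gu$gmax, gu$gmid, gu$gmin),
               tolerance = 1e-10)
  # without unwrapping the naive spectrum would be ~5 nm wide
  expect_lt(g$gmax, 1)
})

test_that("a planted flat monolayer keeps Gmin near the single-peptide value", {
  pc <- plant_configuration(synthetic_spec(4, partitions = list(list(1:4)),
                                           conformations = "surface-bent",
                                           adsorbed = TRUE, slab = TRUE,
                                           n_frames = 3, noise = 0.01,
                                           seed = 8))
  g <- gyration_spectrum(pc$traj, 2, 1:4)
  sp <- single_peptide_spectrum(pc$traj, window_ns = 100)
  expect_equal(g$gmin, mean(sp$gmin), tolerance = 0.1)
  expect_gt(g$gmax, mean(sp$gmax))   # aggregate longer than one molecule
})

test_that("window-averaged single-peptide spectra equal per-frame means", {
  pc <- plant_configuration(synthetic_spec(2, n_frames = 4, stride_ps = 100,
                                           noise = 0, seed = 9))
  sp <- single_peptide_spectrum(pc$traj, window_ns = 0.3)
  # rigid frames: the time average equals the instantaneous value
  g1 <- gyration_spectrum(pc$traj, 1, 1)
  expect_equal(sp$gmax[1], g1$gmax, tolerance = 1e-10)
  # extended conformer has larger Gmax than a compact one
  pcx <- plant_configuration(synthetic_spec(
    2, conformations = c("beta", "surface-bent"), noise = 0, seed = 10))
  spx <- single_peptide_spectrum(pcx$traj, window_ns = 100)
  expect_gt(spx$gmax[1], spx$gmax[2])
})
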