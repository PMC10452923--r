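test_that("peptide builds are deterministic and geometrically sane", {
  b1 <- build_peptide("beta")
  b2 <- build_peptide("beta")
  expect_identical(b1$xyz, b2$xyz)
  c1 <- build_peptide("coil", seed = 9)
  c2 <- build_peptide("coil", seed = 9)
  expect_identical(c1$xyz, c2$xyz)
  expect_false(identical(c1$xyz, build_peptide("coil", seed = 10)$xyz))

  # ideal beta rise per residue ~ 3.3 A: end-to-end of 7 Calpha ~ 6 * 3.3 A
  ca <- b1$xyz[b1$atoms$name == "CA", ]
  e2e <- 10 * sqrt(sum((ca[7, ] - ca[1, ])^2))
  expect_equal(e2e, 6 * 3.3, tolerance = 0.1)

  # surface-bent build lies flat with phenylalanine pseudo-atoms lowest
  bs <- build_peptide("surface-bent")
  fcb <- bs$atoms$name == "CB" & bs$atoms$resname == "PHE"
  expect_lt(mean(bs$xyz[fcb, 3]), mean(bs$xyz[, 3]))
  expect_lt(diff(range(bs$xyz[, 3])), 0.6)
})

test_that("planted configurations close the generator-analyzer loop at zero noise", {
  sp <- plant_configuration(synthetic_spec(
    4, partitions = list(list(c(1, 2), c(3, 4))), noise = 0, seed = 20))
  expect_true(same_partition(partition_frame(sp$traj, 1)$clusters,
                             list(c(1, 2), c(3, 4))))

  mono <- plant_configuration(synthetic_spec(
    8, partitions = list(list(1:8)), conformations = "surface-bent",
    adsorbed = TRUE, slab = TRUE, noise = 0, seed = 21))
  expect_equal(classify_adsorption(mono$traj)$label, "monolayer")
  expect_true(same_partition(partition_frame(mono$traj, 1)$clusters,
                             list(1:8)))

  ra <- ramachandran(mono$traj, 100)
  expect_equal(unname(ra$quadrants), unname(mono$truth$quadrants),
               tolerance = 1e-12)
})

test_that("planted truths are recovered at small noise across random specs", {
  set.seed(52)
  n_ok <- 0; n_tot <- 0
  for (s in 1:30) {
    n <- sample(4:8, 1)
    # random partition of 1..n
    grp <- sort(sample(1:3, n, replace = TRUE))
    part <- unname(split(seq_len(n), grp))
    pc <- plant_configuration(synthetic_spec(
      n, partitions = list(part), conformations = "beta", n_frames = 2,
      noise = 0.02, seed = 1000 + s))
    for (f in 1:2) {
      n_tot <- n_tot + 1
      n_ok <- n_ok + same_partition(partition_frame(pc$traj, f)$clusters,
                                    pc$truth$partitions[[f]])
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("infeasible packings and invalid planted partitions error", {
  expect_error(synthetic_spec(4, partitions = list(list(c(1, 2), c(2, 3, 4)))),
               "exactly once")
  expect_error(synthetic_spec(4, adsorbed = TRUE, slab = FALSE), "slab")
})

test_that("the Langevin aggregator is deterministic and conserves connectivity", {
  p <- langevin_params(seed = 23)
  s0 <- langevin_system(3, c(3.5, 3.5, 3.5), spacing = 1.1)
  t1 <- langevin_aggregate(p, s0, n_steps = 600, stride = 100)
  t2 <- langevin_aggregate(p, s0, n_steps = 600, stride = 100)
  expect_identical(t1$coords, t2$coords)
  # byte-identical emitted files for the same seed
  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(t1$system, t1$coords[, , n_frames(t1)], t1$box[[1]], f1)
  write_gro(t2$system, t2$coords[, , n_frames(t2)], t2$box[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  # bonds never exceed twice their rest length at stable parameters
  for (f in seq_len(n_frames(t1))) {
    for (i in 1:3) {
      idx <- which(t1$system$atoms$peptide == i)
      d <- sqrt(rowSums(diff(t1$coords[idx, , f])^2))
      expect_lt(max(d), 2 * p$bond_length)
    }
  }
})

test_that("dilute non-interacting chains do not aggregate spuriously", {
  p0 <- langevin_params(eps_hh = 0, eps_qq_attr = 0, eps_qq_rep = 0,
                        seed = 24)
  s0 <- langevin_system(4, c(4.5, 4.5, 4.5), spacing = 1.5)
  tr <- langevin_aggregate(p0, s0, n_steps = 1000, stride = 100)
  expect_equal(max(largest_oligomer_series(tr)$size), 1L)
})

test_that("strong attraction drives full aggregation in most seeds", {
  hits <- 0
  for (s in 1:20) {
    p <- langevin_params(eps_hh = 25, w = 0.15, cutoff = 1.4, seed = 100 + s)
    s0 <- langevin_system(4, c(2.6, 2.6, 2.6), spacing = 0.85)
    tr <- langevin_aggregate(p, s0, n_steps = 8000, stride = 2000)
    hits <- hits + (max(lengths(partition_frame(
      tr, n_frames(tr))$clusters)) == 4L)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("phenylalanine-wall attraction orders residue heights as on gold", {
  p <- langevin_params(seed = 25)
  s0 <- langevin_system(2, c(3, 3, 3), slab = TRUE, spacing = 1.2)
  tr <- langevin_aggregate(p, s0, n_steps = 6000, stride = 500)
  late <- (n_frames(tr) - 5):n_frames(tr)
  zf <- mean(tr$coords[tr$system$atoms$resname == "PHE", 3, late])
  zke <- mean(tr$coords[tr$system$atoms$resname %in% c("LYS", "GLU"), 3, late])
  expect_lt(zf, zke)
})
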