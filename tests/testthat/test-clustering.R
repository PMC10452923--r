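# Planted two-bead "peptides": one heavy CA bead per residue lets exact
# pair distances be engineered.

two_bead_traj <- function(gap, n_res = 2) {
  p1 <- cbind(seq_len(n_res), 0, 0)
  p2 <- cbind(seq_len(n_res), gap, 0)
  bead_traj(list(p1, p2), resnames = c("LYS", "GLU"))
}

test_that("the contact criterion is heavy-atom and strictly below cutoff", {
  expect_true(peptide_contact(two_bead_traj(0.39), 1, 1, 2))
  expect_false(peptide_contact(two_bead_traj(0.40), 1, 1, 2))   # boundary
  expect_true(peptide_contact(two_bead_traj(0.399999), 1, 1, 2))
  expect_error(peptide_contact(two_bead_traj(0.1), 1, 2, 2), "differ")

  # peptides touching only via hydrogens do not count
  atoms <- data.frame(name = rep(c("CA", "HA"), 2), element = rep(c("C", "H"), 2),
                      resname = "ALA", resid = 1L, peptide = rep(1:2, each = 2),
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  xyz <- rbind(c(0, 0, 0), c(0.25, 0, 0),    # heavy at 0.5, H in between
               c(0.5, 0, 0.001), c(0.3, 0, 0.001))
  tr <- trajectory(sys, xyz, 0, box_spec(c(10, 10, 10)))
  expect_false(peptide_contact(tr, 1, 1, 2))
})

test_that("single-linkage transitivity joins chains of contacts", {
  # A-B and B-C in contact, A-C far apart -> one cluster
  tr <- bead_traj(list(cbind(0, 0, 0), cbind(0.35, 0, 0), cbind(0.70, 0, 0)),
                  resnames = "ALA")
  part <- partition_frame(tr, 1)
  expect_equal(part$clusters, list(1:3))
  # no contacts -> all singletons
  tr2 <- bead_traj(list(cbind(0, 0, 0), cbind(2, 0, 0), cbind(4, 0, 0)),
                   resnames = "ALA")
  expect_equal(lengths(partition_frame(tr2, 1)$clusters), c(1, 1, 1))
})

test_that("partitions agree with the brute-force oracle on random and boundary frames", {
  skip_if_not_installed("igraph")
  set.seed(7)
  n_match <- 0; n_tot <- 0
  for (k in 1:60) {
    n <- sample(3:6, 1)
    coords <- lapply(seq_len(n), function(i)
      sweep(matrix(runif(9, 0, 0.4), 3), 2, runif(3, 0, 2.6), "+"))
    tr <- bead_traj(coords, box_len = c(3, 3, 3),
                    resnames = c("LYS", "LEU", "VAL"))
    got <- partition_frame(tr, 1)$clusters
    want <- oracle_partition(tr, 1)
    n_tot <- n_tot + 1
    n_match <- n_match + same_partition(got, want)
  }
  expect_equal(n_match, n_tot)

  # engineered exact-boundary frame: pair at exactly 0.40 nm must stay apart
  trb <- bead_traj(list(cbind(0, 0, 0), cbind(0.4, 0, 0), cbind(0.79, 0, 0)),
                   resnames = "ALA")
  expect_true(same_partition(partition_frame(trb, 1)$clusters,
                             oracle_partition(trb, 1)))
  expect_equal(lengths(partition_frame(trb, 1)$clusters), c(2, 1))
})

test_that("partitioning is permutation-equivariant and monotone in cutoff", {
  set.seed(11)
  coords <- lapply(1:5, function(i)
    sweep(matrix(runif(6, 0, 0.3), 2), 2, runif(3, 0, 2), "+"))
  tr <- bead_traj(coords, box_len = c(4, 4, 4), resnames = c("LYS", "GLU"))
  base <- partition_frame(tr, 1)$clusters
  perm <- sample(5)
  trp <- bead_traj(coords[perm], box_len = c(4, 4, 4),
                   resnames = c("LYS", "GLU"))
  got <- partition_frame(trp, 1)$clusters
  relabelled <- lapply(got, function(cl) sort(perm[cl]))
  expect_true(same_partition(relabelled, base))

  for (cut in c(0.2, 0.4, 0.8, 1.6)) {
    s1 <- max(lengths(partition_frame(tr, 1, cut)$clusters))
    s2 <- max(lengths(partition_frame(tr, 1, cut * 2)$clusters))
    expect_lte(s1, s2)
  }
})

test_that("largest-oligomer series follows a planted aggregation event", {
  parts <- c(rep(list(as.list(1:4)), 5), rep(list(list(1:4)), 5))
  pc <- plant_configuration(synthetic_spec(4, partitions = parts,
                                           n_frames = 10, stride_ps = 100,
                                           noise = 0, seed = 2))
  s <- largest_oligomer_series(pc$traj)
  expect_equal(s$size, c(rep(1L, 5), rep(4L, 5)))
  expect_true(all(s$size <= 4))

  pc1 <- plant_configuration(synthetic_spec(1, noise = 0, seed = 3))
  expect_equal(largest_oligomer_series(pc1$traj)$size, 1L)
})

test_that("size histogram uses peptide weighting by default, cluster weighting on request", {
  # half the frames 2+2, half a single 4-mer
  parts <- c(rep(list(list(c(1, 2), c(3, 4))), 5), rep(list(list(1:4)), 5))
  pc <- plant_configuration(synthetic_spec(4, partitions = parts,
                                           n_frames = 10, stride_ps = 100,
                                           noise = 0, seed = 4))
  h <- size_histogram(pc$traj, window_ns = 9e-4 * 1000)  # whole run
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(unname(h$p[c("2", "4")]), c(0.5, 0.5))
  hc <- size_histogram(pc$traj, window_ns = 0.9, weighting = "cluster")
  expect_equal(unname(hc$p[c("2", "4")]), c(2 / 3, 1 / 3))

  # pure state: all frames one 4-mer
  pc2 <- plant_configuration(synthetic_spec(4, partitions = list(list(1:4)),
                                            n_frames = 4, stride_ps = 100,
                                            noise = 0, seed = 5))
  h2 <- size_histogram(pc2$traj, window_ns = 0.3)
  expect_equal(unname(h2$p), c(0, 0, 0, 1))

  expect_error(size_histogram(pc2$traj, window_ns = 100), "window")
})
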