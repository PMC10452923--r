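collinear_ref <- function(spacing = 0.38, R = 7)
  reference_from_coordinates(cbind(spacing * (seq_len(R) - 1), 0, 0),
                             "collinear")

test_that("reference distance sets have the canonical size and ordering", {
  ref <- collinear_ref()
  expect_length(ref$r, 21)            # R(R-1)/2 for R = 7
  # lexicographic pair order: (1,2), (1,3), ..., (1,7), (2,3), ...
  expect_equal(ref$r[1:6], 0.38 * (1:6), tolerance = 1e-12)
  expect_equal(ref$r[7], 0.38, tolerance = 1e-12)    # pair (2,3)
  expect_equal(max(ref$r), 0.38 * 6, tolerance = 1e-12)
  expect_error(reference_from_coordinates(rbind(c(0, 0, 0), c(0, 0, 0),
                                                c(1, 0, 0))), "duplicate")
})

test_that("reference distances survive a text-file round trip", {
  ref <- reference_fibril()
  f <- withr::local_tempfile(fileext = ".dat")
  write_reference(ref, f)
  back <- read_reference(f, "fibril")
  expect_equal(back$r, ref$r, tolerance = 1e-9)
  expect_equal(back$n_residues, 7L)
})

test_that("DRMSD is zero on identity and invariant under rigid motions and reflection", {
  set.seed(41)
  bp <- build_peptide("beta")
  ca <- bp$xyz[bp$atoms$name == "CA", ]
  ref <- reference_from_coordinates(ca, "self")
  expect_equal(drmsd(ca, ref), 0, tolerance = 1e-12)
  for (k in 1:100) {
    Rot <- random_rotation()
    x <- sweep(ca %*% t(Rot), 2, runif(3, -5, 5), "+")
    if (k %% 2 == 0) x[, 3] <- -x[, 3]      # reflection
    expect_equal(drmsd(x, ref), 0, tolerance = 1e-10)
  }
})

test_that("DRMSD agrees with an independent brute-force pair-sum oracle", {
  # frozen golden value: collinear 0.38 nm chain vs the same chain with the
  # last Calpha displaced perpendicular by 0.38 nm (21-pair brute force)
  qry <- cbind(0.38 * (0:6), 0, 0)
  qry[7, ] <- c(0.38 * 6, 0.38, 0)
  expect_equal(drmsd(qry, collinear_ref()), 0.4430316863, tolerance = 1e-9)

  oracle_drmsd <- function(a, b) {
    s <- 0; n <- 0
    for (p in 1:(nrow(a) - 1)) for (q in (p + 1):nrow(a)) {
      s <- s + (sqrt(sum((a[p, ] - a[q, ])^2)) -
                sqrt(sum((b[p, ] - b[q, ])^2)))^2
      n <- n + 1
    }
    10 * sqrt(s / n)
  }
  set.seed(42)
  for (k in 1:20) {
    a <- matrix(rnorm(21, sd = 0.5), 7)
    b <- matrix(rnorm(21, sd = 0.5), 7)
    expect_equal(drmsd(a, reference_from_coordinates(b)),
                 oracle_drmsd(a, b), tolerance = 1e-10)
  }
})

test_that("DRMSD is a pseudometric sensitive to any single pair change", {
  set.seed(43)
  a <- matrix(rnorm(21, sd = 0.5), 7)
  b <- matrix(rnorm(21, sd = 0.5), 7)
  c_ <- matrix(rnorm(21, sd = 0.5), 7)
  dab <- drmsd(a, reference_from_coordinates(b))
  expect_equal(dab, drmsd(b, reference_from_coordinates(a)),
               tolerance = 1e-10)                          # symmetry
  dac <- drmsd(a, reference_from_coordinates(c_))
  dcb <- drmsd(c_, reference_from_coordinates(b))
  expect_lte(dab, dac + dcb + 1e-10)                       # triangle
  b2 <- b; b2[1, ] <- b2[1, ] + c(0.2, 0, 0)
  expect_gt(drmsd(b2, reference_from_coordinates(b)), 0)   # strict positivity
})

test_that("DRMSD histograms separate planted ensembles", {
  # frozen fixture: all peptides at the fibril reference -> delta at bin 0
  pc <- plant_configuration(synthetic_spec(4, conformations = "beta",
                                           noise = 0, seed = 13))
  dh <- drmsd_histograms(pc$traj, list(fibril = reference_fibril()),
                         window_ns = 100)
  h <- dh$fibril$hist
  expect_equal(sum(h$density) * dh$fibril$bin, 1, tolerance = 1e-9)
  expect_equal(h$mid[which(h$density > 0)], 0.05)

  # half beta, half surface-bent -> planted 0.5/0.5 bimodal mass
  pcm <- plant_configuration(synthetic_spec(
    4, conformations = c("beta", "beta", "surface-bent", "surface-bent"),
    noise = 0, seed = 14))
  dhm <- drmsd_histograms(pcm$traj, list(fibril = reference_fibril()),
                          window_ns = 100)
  hm <- dhm$fibril$hist
  below <- sum(hm$density[hm$mid < 1]) * dhm$fibril$bin
  expect_equal(below, 0.5, tolerance = 1e-9)

  # beta-rich ensemble scores below 1 A against the beta reference far more
  # than against the bent reference
  pcb <- plant_configuration(synthetic_spec(4, conformations = "beta",
                                            noise = 0.02, seed = 15))
  dhb <- drmsd_histograms(pcb$traj, list(fibril = reference_fibril(),
                                         surface = reference_surface()), 100)
  mass_below <- function(x) sum(x$hist$density[x$hist$mid < 1]) * x$bin
  expect_gt(mass_below(dhb$fibril), mass_below(dhb$surface))
})

test_that("torsion angles match an independent oracle", {
  # planar cis/trans cases
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0)
  expect_equal(abs(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                 c(1, 0, 1))), 90)
  skip_if_not_installed("bio3d")
  set.seed(44)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4)
    mine <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    orac <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(mine, as.numeric(orac[!is.na(orac)])[1], tolerance = 1e-6)
  }
})

test_that("Ramachandran densities recover planted dihedrals and quadrants", {
  pc <- plant_configuration(synthetic_spec(3, conformations = "beta",
                                           noise = 0, seed = 16))
  ra <- ramachandran(pc$traj, 100)
  expect_equal(unname(ra$quadrants["upper_left"]), 1)
  expect_equal(sum(ra$density), 1, tolerance = 1e-12)
  expect_equal(mean(ra$angles$phi), -139, tolerance = 1e-6)
  expect_equal(mean(ra$angles$psi), 135, tolerance = 1e-6)

  # planted alpha-helical dihedrals occupy the lower-left quadrant
  hb <- surfagg:::.build_from_dihedrals(rep(-57, 7), rep(-47, 7))
  sys <- molecular_system(hb$atoms)
  tra <- trajectory(sys, hb$xyz, 0, box_spec(c(30, 30, 30)))
  raa <- ramachandran(tra, 100)
  expect_equal(unname(raa$quadrants["lower_left"]), 1)
})

test_that("Ramachandran density recovers the mean of dihedrals drawn from a 2D Gaussian", {
  set.seed(45)
  n_frames <- 30
  mu <- c(phi = -100, psi = 120); sdv <- 12
  frames <- list()
  for (f in seq_len(n_frames)) {
    hb <- surfagg:::.build_from_dihedrals(rnorm(7, mu[1], sdv),
                                          rnorm(7, mu[2], sdv))
    frames[[f]] <- hb$xyz
  }
  sys <- molecular_system(hb$atoms)
  coords <- array(unlist(frames), dim = c(42, 3, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- frames[[f]]
  tr <- trajectory(sys, coords, (seq_len(n_frames) - 1) * 10,
                   box_spec(c(30, 30, 30)))
  ra <- ramachandran(tr, window_ns = 1)
  n <- nrow(ra$angles)
  tol <- max(3 * sdv / sqrt(n), 2)
  expect_lt(abs(mean(ra$angles$phi) - mu[["phi"]]), tol)
  expect_lt(abs(mean(ra$angles$psi) - mu[["psi"]]), tol)
})
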