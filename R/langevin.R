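# Coarse-grained stochastic aggregator: one bead per residue, overdamped
# (position) Langevin dynamics. This is a fixture generator producing
# aggregation-like kinetics (hydrophobic beads attract across peptides,
# like-charged termini repel, unlike attract, phenylalanine beads feel an
# attractive wall when a slab is present); it makes no claim to approximate
# any particular force field.

# residue classes driving the pair interactions (KLVFFAE: charged termini
# K+/E-, hydrophobic core)
.RES_CLASS <- c(LYS = "pos", LEU = "hyd", VAL = "hyd", PHE = "hyd",
                ALA = "hyd", GLU = "neg")

#' Parameters of the Langevin bead-chain aggregator
#'
#' Energies in kJ/mol, lengths in nm, time in ps. The default temperature
#' term kT = 2.494 kJ/mol corresponds to 300 K.
#'
#' @param bond_length backbone bead spacing (0.38 nm, the Calpha virtual
#'   bond).
#' @param k_bond,k_13 harmonic stiffnesses of bonded (1-2) and
#'   next-nearest (1-3) bead distances, kJ/mol/nm^2 (the 1-3 term is the
#'   chain's bending stiffness).
#' @param r13 rest length of the 1-3 term, nm (< 2*bond_length: semi-
#'   flexible chain).
#' @param sigma_rep,k_rep excluded-volume diameter (nm) and stiffness.
#' @param eps_hh,eps_qq_attr,eps_qq_rep Gaussian-well depths (kJ/mol):
#'   hydrophobic-hydrophobic attraction, opposite-charge attraction,
#'   like-charge repulsion.
#' @param r0,w position and width of the interaction well, nm.
#' @param wall_eps,wall_z0,wall_w attractive wall acting on PHE beads:
#'   depth (kJ/mol), height of the minimum above the top slab layer and
#'   width (nm).
#' @param kT thermal energy, kJ/mol.
#' @param gamma friction, amu/ps.
#' @param dt timestep, ps.
#' @param cutoff non-bonded interaction cutoff, nm.
#' @param seed RNG seed (all randomness flows from it).
#' @return object of class `"langevin_params"`.
#' @export
langevin_params <- function(bond_length = 0.38, k_bond = 800, k_13 = 15,
                            r13 = 0.62, sigma_rep = 0.34, k_rep = 400,
                            eps_hh = 14, eps_qq_attr = 10, eps_qq_rep = 6,
                            r0 = 0.38, w = 0.10,
                            wall_eps = 12, wall_z0 = 0.30, wall_w = 0.15,
                            kT = 2.494, gamma = 60, dt = 0.002,
                            cutoff = 1.2, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$k_bond > 0, p$k_13 > 0, p$k_rep > 0, p$gamma > 0, p$dt > 0)
  structure(p, class = "langevin_params")
}

#' Initial bead-chain configuration
#'
#' Extended one-bead-per-residue chains laid out on a grid, at least
#' `spacing` apart.
#'
#' @param n_peptides peptide count.
#' @param box_len length-3 box edges, nm.
#' @param slab attach a surface model (top layer at z = 0, box periodic in
#'   x/y only)?
#' @param spacing grid spacing between chains, nm.
#' @param resnames residue sequence.
#' @return list with `system`, `xyz`, `box` — the `system0` argument of
#'   [langevin_aggregate()].
#' @export
langevin_system <- function(n_peptides = 4L, box_len = c(4, 4, 4),
                            slab = FALSE, spacing = 1.2,
                            resnames = .SEQ3) {
  R <- length(resnames)
  atoms <- do.call(rbind, lapply(seq_len(n_peptides), function(i)
    data.frame(name = "CA", element = "C", resname = resnames,
               resid = seq_len(R), peptide = i, chain = "A",
               mass = unname(.SC_MASS[resnames]) + 56,
               stringsAsFactors = FALSE)))
  surface <- if (slab) surface_model(lx = box_len[1], ly = box_len[2],
                                     top_z = 0) else NULL
  sys <- molecular_system(atoms, surface = surface)
  per_row <- max(1L, floor(box_len[2] / spacing))
  z0 <- if (slab) 1.0 else box_len[3] / 2
  xyz <- do.call(rbind, lapply(seq_len(n_peptides), function(i) {
    row <- (i - 1L) %% per_row
    lev <- (i - 1L) %/% per_row
    cbind(0.4 + (seq_len(R) - 1) * 0.38,
          0.5 + row * spacing,
          z0 + lev * spacing)
  }))
  box <- box_spec(box_len, periodic = c(TRUE, TRUE, !slab))
  list(system = sys, xyz = xyz, box = box)
}

#' Run the overdamped Langevin aggregator
#'
#' Position-Langevin update per bead:
#' `x <- x + F*dt/gamma + sqrt(2*kT*dt/gamma) * N(0,1)`. Periodic in x/y
#' (and z without a slab); with a slab, beads are confined between a soft
#' repulsive floor just above the top layer and a soft ceiling, and PHE
#' beads feel the attractive wall. Deterministic given the seed.
#'
#' @param params a [langevin_params()].
#' @param system0 initial configuration from [langevin_system()].
#' @param n_steps number of integration steps.
#' @param stride emit every `stride`-th step (frame times in ps).
#' @return a `"traj"`.
#' @export
langevin_aggregate <- function(params, system0, n_steps = 5000L,
                               stride = 100L) {
  sys <- system0$system
  box <- system0$box
  x <- system0$xyz
  n <- nrow(x)
  R <- sys$n_residues
  pep <- sys$atoms$peptide
  cls <- .RES_CLASS[sys$atoms$resname]
  slab <- !is.null(sys$surface)

  # bonded index pairs (1-2 and 1-3 within each chain)
  b12 <- do.call(rbind, lapply(split(seq_len(n), pep), function(ix)
    cbind(ix[-length(ix)], ix[-1])))
  b13 <- do.call(rbind, lapply(split(seq_len(n), pep), function(ix)
    if (length(ix) > 2) cbind(ix[1:(length(ix) - 2)], ix[3:length(ix)])
    else NULL))
  # non-bonded pairs: different peptides, or same peptide >= 3 apart
  allp <- t(combn(n, 2))
  sep <- abs(sys$atoms$resid[allp[, 1]] - sys$atoms$resid[allp[, 2]])
  nb <- allp[pep[allp[, 1]] != pep[allp[, 2]] |
             (pep[allp[, 1]] == pep[allp[, 2]] & sep >= 3), , drop = FALSE]
  # well depth per non-bonded pair (positive = attractive)
  c1 <- cls[nb[, 1]]; c2 <- cls[nb[, 2]]
  inter <- pep[nb[, 1]] != pep[nb[, 2]]
  epsv <- numeric(nrow(nb))
  epsv[inter & c1 == "hyd" & c2 == "hyd"] <- params$eps_hh
  epsv[inter & ((c1 == "pos" & c2 == "neg") |
                (c1 == "neg" & c2 == "pos"))] <- params$eps_qq_attr
  epsv[inter & c1 == c2 & c1 %in% c("pos", "neg")] <- -params$eps_qq_rep
  phe <- sys$atoms$resname == "PHE"

  nf <- floor(n_steps / stride)
  coords <- array(NA_real_, dim = c(n, 3, nf))
  times <- numeric(nf)
  noise_sd <- sqrt(2 * params$kT * params$dt / params$gamma)
  mob <- params$dt / params$gamma
  zfloor <- 0.2; zceil <- box$lengths[3] - 0.2

  .with_seed(params$seed, {
    fi <- 0L
    for (step in seq_len(n_steps)) {
      F <- matrix(0, n, 3)
      # harmonic bonded terms
      for (bl in list(list(p = b12, r0 = params$bond_length, k = params$k_bond),
                      list(p = b13, r0 = params$r13, k = params$k_13))) {
        d <- x[bl$p[, 1], , drop = FALSE] - x[bl$p[, 2], , drop = FALSE]
        d <- .min_image(d, box)
        r <- sqrt(rowSums(d * d))
        fmag <- -2 * bl$k * (r - bl$r0) / pmax(r, 1e-6)
        fp <- d * fmag
        F <- F + .accum(fp, bl$p, n)
      }
      # non-bonded: soft core + Gaussian well
      d <- x[nb[, 1], , drop = FALSE] - x[nb[, 2], , drop = FALSE]
      d <- .min_image(d, box)
      r2 <- rowSums(d * d)
      act <- which(r2 < params$cutoff^2)
      if (length(act)) {
        da <- d[act, , drop = FALSE]
        r <- sqrt(r2[act])
        fmag <- numeric(length(act))
        ov <- r < params$sigma_rep
        fmag[ov] <- fmag[ov] + 2 * params$k_rep * (params$sigma_rep - r[ov])
        dr <- r - params$r0
        # F = -dU/dr with U = -eps * exp(-dr^2 / (2 w^2))
        fmag <- fmag - epsv[act] * dr / params$w^2 *
          exp(-dr^2 / (2 * params$w^2))
        fp <- da * (fmag / pmax(r, 1e-6))
        F <- F + .accum(fp, nb[act, , drop = FALSE], n)
      }
      if (slab) {
        z <- x[, 3]
        low <- z < zfloor
        F[low, 3] <- F[low, 3] + 2 * params$k_rep * (zfloor - z[low])
        hi <- z > zceil
        F[hi, 3] <- F[hi, 3] - 2 * params$k_rep * (z[hi] - zceil)
        dz <- z[phe] - params$wall_z0
        F[phe, 3] <- F[phe, 3] - params$wall_eps * dz / params$wall_w^2 *
          exp(-dz^2 / (2 * params$wall_w^2))
      }
      x <- x + F * mob + matrix(rnorm(3L * n, sd = noise_sd), n, 3)
      if (anyNA(x) || any(!is.finite(x)))
        stop("langevin_aggregate: coordinate overflow at step ", step,
             " (seed ", params$seed, ")")
      if (step %% stride == 0L) {
        fi <- fi + 1L
        coords[, , fi] <- x
        times[fi] <- step * params$dt
      }
    }
  })
  trajectory(sys, coords[, , seq_len(nf), drop = FALSE], times, box)
}

# Accumulate +f on pairs[,1] and -f on pairs[,2].
.accum <- function(f, pairs, n) {
  out <- matrix(0, n, 3)
  s1 <- rowsum(f, pairs[, 1])
  out[as.integer(rownames(s1)), ] <- out[as.integer(rownames(s1)), ] + s1
  s2 <- rowsum(f, pairs[, 2])
  out[as.integer(rownames(s2)), ] <- out[as.integer(rownames(s2)), ] - s2
  out
}
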