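# fcc(111) slab geometry and peptide--surface analyses.
#
# The reference construction is a gold (111) surface: in-plane
# nearest-neighbour spacing a/sqrt(2) for lattice parameter a (4.14 A for
# Au), interlayer spacing a/sqrt(3), ABC stacking. A "unit cell" here is the
# rectangular two-atom surface cell of dimensions d x d*sqrt(3)/... see
# build_slab(); 20 x 12 such cells give the 5.860 nm x 6.090 nm slab used
# throughout the examples.

.N_AVOGADRO <- 6.02214076e23

# Top atomic layer: maximum z over slab atoms, with membership of the layer
# decided by a 0.5 A tolerance band.
.top_layer_z <- function(z, tol = 0.05) {
  zmax <- max(z)
  mean(z[z > zmax - tol])
}

.count_layers <- function(z, tol = 0.05) {
  zs <- sort(z)
  sum(diff(zs) > tol) + 1L
}

#' Surface slab metadata
#'
#' @param lx,ly in-plane slab dimensions in nm.
#' @param top_z z of the top atomic layer in nm.
#' @param layers number of atomic layers.
#' @param a lattice parameter in Angstrom (4.14 for Au).
#' @param nx,ny unit-cell counts, when built by [build_slab()].
#' @return object of class `"surface_model"`.
#' @export
surface_model <- function(lx, ly, top_z = 0, layers = 5L, a = 4.14,
                          nx = NA_integer_, ny = NA_integer_) {
  stopifnot(lx > 0, ly > 0, layers >= 1L)
  structure(list(lx = lx, ly = ly, top_z = top_z, layers = as.integer(layers),
                 a = a, nx = nx, ny = ny),
            class = "surface_model")
}

#' Build an fcc(111) slab
#'
#' Atoms are laid out in ABC-stacked (111) layers. Each layer is `nx * ny`
#' rectangular two-atom cells of dimensions `d x d*sqrt(3)` with
#' `d = a/sqrt(2)` the nearest-neighbour spacing, so the in-plane slab
#' dimensions are `nx*d` by `ny*d*sqrt(3)` and the atom count is
#' `nx * ny * 2 * layers`. Layers are `a/sqrt(3)` apart, each shifted
#' laterally to the hollow site of the one above; the stacking offsets
#' repeat with period 3. The top layer sits at z = 0, deeper layers at
#' negative z.
#'
#' @param a lattice parameter in Angstrom (default 4.14, gold).
#' @param nx,ny surface unit-cell counts (defaults 20 x 12).
#' @param layers atomic layer count (default 5).
#' @return list with `xyz` (atom coordinates in nm), `model`
#'   (a [surface_model()]) and `atoms` (data.frame of Au atom records).
#' @export
build_slab <- function(a = 4.14, nx = 20L, ny = 12L, layers = 5L) {
  stopifnot(a > 0, nx >= 1L, ny >= 1L, layers >= 1L)
  d <- a / sqrt(2) / 10          # nn spacing, nm
  lx <- nx * d
  ly <- ny * d * sqrt(3)
  dz <- a / sqrt(3) / 10         # (111) interlayer spacing, nm
  # two-atom rectangular basis of the triangular lattice
  basis <- rbind(c(0, 0), c(d / 2, d * sqrt(3) / 2))
  # lateral offset between consecutive (111) layers (to the hollow site)
  layer_shift <- c(d / 2, d / (2 * sqrt(3)))
  cells <- as.matrix(expand.grid(x = (seq_len(nx) - 1) * d,
                                 y = (seq_len(ny) - 1) * d * sqrt(3)))
  out <- vector("list", layers)
  for (l in seq_len(layers)) {
    sh <- ((l - 1L) %% 3L) * layer_shift
    pts <- rbind(cbind(cells[, 1] + basis[1, 1] + sh[1],
                       cells[, 2] + basis[1, 2] + sh[2]),
                 cbind(cells[, 1] + basis[2, 1] + sh[1],
                       cells[, 2] + basis[2, 2] + sh[2]))
    pts[, 1] <- pts[, 1] %% lx
    pts[, 2] <- pts[, 2] %% ly
    out[[l]] <- cbind(pts, -(l - 1L) * dz)
  }
  xyz <- do.call(rbind, out)
  model <- surface_model(lx = lx, ly = ly, top_z = 0, layers = layers,
                         a = a, nx = as.integer(nx), ny = as.integer(ny))
  atoms <- data.frame(name = "AU", element = "AU", resname = "AU",
                      resid = NA_integer_, peptide = NA_integer_,
                      chain = "Z", mass = .ELEMENT_MASS[["AU"]],
                      stringsAsFactors = FALSE)
  atoms <- atoms[rep(1L, nrow(xyz)), ]
  rownames(atoms) <- NULL
  list(xyz = xyz, model = model, atoms = atoms)
}

#' Areal peptide surface density
#'
#' `n / (N_A * Lx * Ly)` in mol m^-2: four peptides on the 5.860 nm x
#' 6.090 nm slab give 1.86e-7 mol m^-2.
#'
#' @param n_peptides peptide count.
#' @param lx,ly in-plane slab dimensions in nm.
#' @return density in mol m^-2.
#' @export
surface_density <- function(n_peptides, lx, ly) {
  stopifnot(n_peptides >= 0, lx > 0, ly > 0)
  n_peptides / (.N_AVOGADRO * (lx * 1e-9) * (ly * 1e-9))
}

#' Residue and peptide z-profiles above the surface
#'
#' Heights are reported relative to the top atomic layer. The residue
#' profile is the window mean of each residue's centre-of-mass z; the
#' peptide series is the centre-of-mass z of every peptide at every frame
#' (not only the window), for adsorption kinetics.
#'
#' @param traj a `"traj"` whose system has a surface.
#' @param window_ns trailing-window length in ns.
#' @return object of class `"z_profile"`: `residue` (R x Nmol matrix of mean
#'   z - z_top in nm), `com_series` (data.frame time, peptide, z).
#' @export
z_profile <- function(traj, window_ns = 100) {
  sys <- traj$system
  if (is.null(sys$surface)) stop("system has no surface model")
  ztop <- sys$surface$top_z
  n <- sys$n_peptides
  R <- sys$n_residues
  fr <- suppressWarnings(.window_frames(traj, window_ns))
  res_z <- matrix(0, R, n, dimnames = list(residue_labels(sys), seq_len(n)))
  com <- expand.grid(frame = seq_len(n_frames(traj)), peptide = seq_len(n))
  com$time <- traj$times[com$frame]
  com$z <- NA_real_
  m <- sys$atoms$mass
  for (i in seq_len(n)) {
    pidx <- .pep_idx(sys, i)
    wi <- m[pidx] / sum(m[pidx])
    for (f in seq_len(n_frames(traj))) {
      z <- traj$coords[pidx, 3, f]
      com$z[com$frame == f & com$peptide == i] <- sum(wi * z) - ztop
    }
    for (r in seq_len(R)) {
      ridx <- .pep_idx(sys, i, resid = r)
      wr <- m[ridx] / sum(m[ridx])
      res_z[r, i] <- mean(vapply(fr, function(f)
        sum(wr * traj$coords[ridx, 3, f]), numeric(1))) - ztop
    }
  }
  structure(list(residue = res_z,
                 com_series = com[order(com$frame, com$peptide),
                                  c("time", "peptide", "z")]),
            class = "z_profile")
}

#' Classify peptide adsorption and aggregate layering
#'
#' A peptide is adsorbed when at least one of its heavy atoms lies within
#' `contact_z` of the top-layer z in at least `persistence` of the window
#' frames. The aggregate label is `"monolayer"` when every peptide is
#' adsorbed, `"detached"` when none is, `"multilayer"` otherwise.
#'
#' @param traj a `"traj"` whose system has a surface.
#' @param window_ns trailing-window length in ns.
#' @param contact_z surface-contact threshold above the top layer, nm.
#' @param persistence minimum fraction of window frames in contact.
#' @return list with `adsorbed` (logical per peptide), `contact_fraction`
#'   (numeric per peptide) and `label`.
#' @export
classify_adsorption <- function(traj, window_ns = 100, contact_z = 0.5,
                                persistence = 0.5) {
  sys <- traj$system
  if (is.null(sys$surface)) stop("system has no surface model")
  zcut <- sys$surface$top_z + contact_z
  fr <- suppressWarnings(.window_frames(traj, window_ns))
  n <- sys$n_peptides
  frac <- vapply(seq_len(n), function(i) {
    hidx <- .pep_idx(sys, i, heavy_only = TRUE)
    mean(vapply(fr, function(f) any(traj$coords[hidx, 3, f] <= zcut),
                logical(1)))
  }, numeric(1))
  adsorbed <- frac >= persistence
  label <- if (all(adsorbed)) "monolayer"
           else if (!any(adsorbed)) "detached"
           else "multilayer"
  list(adsorbed = adsorbed, contact_fraction = frac, label = label)
}
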