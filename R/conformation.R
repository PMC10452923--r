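# Conformational classification: distance-RMSD against reference
# conformations and Ramachandran (phi, psi) densities.
#
# The distance RMSD between a peptide conformation and a reference is the
# root-mean-square difference over all intramolecular Calpha-Calpha pair
# distances,
#
#   DRMSD = sqrt( (1/N) * sum_i (r_i - r_i_ref)^2 ),  N = R(R-1)/2,
#
# computed internally in nm and reported in Angstrom. Being built from
# internal distances only, it needs no superposition and is invariant under
# rigid motions and reflection (mirror images are indistinguishable — a
# property of the metric, not corrected here).

#' Reference Calpha-Calpha distance set
#'
#' @param coords R x 3 matrix of Calpha coordinates in nm (R >= 3).
#' @param label reference name, e.g. `"fibril"` or `"surface"`.
#' @return object of class `"refdist"`: `label`, `r` (vector of the
#'   R(R-1)/2 pair distances in nm, lexicographic over pairs (p, q), p < q),
#'   `n_residues`.
#' @export
reference_from_coordinates <- function(coords, label = "reference") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  R <- nrow(coords)
  if (R < 3L) stop("need at least 3 Calpha positions")
  d <- .ca_pair_distances(coords)
  if (any(d < 1e-9))
    stop("duplicate Calpha coordinates in reference '", label, "'")
  structure(list(label = label, r = d, n_residues = R), class = "refdist")
}

# Lexicographic (p < q) pair distances of an R x 3 coordinate matrix.
.ca_pair_distances <- function(coords) {
  R <- nrow(coords)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                coords[pairs[, 2], , drop = FALSE])^2))
}

#' Read a reference conformation from file
#'
#' Accepts a PDB file (Calpha atoms of the first chain are extracted;
#' coordinates converted Angstrom to nm) or a plain-text distance file: one
#' header line, then R(R-1)/2 whitespace-separated distances in nm in the
#' canonical pair order.
#'
#' @param path file path (`.pdb` or text).
#' @param label reference name.
#' @export
read_reference <- function(path, label = "reference") {
  if (tolower(tools::file_ext(path)) == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    ca <- matrix(pdb$xyz[1, sel$xyz], ncol = 3, byrow = TRUE) / 10
    ch <- pdb$atom$chain[sel$atom]
    if (length(unique(ch)) > 1L) ca <- ca[ch == ch[1], , drop = FALSE]
    return(reference_from_coordinates(ca, label))
  }
  ln <- readLines(path, warn = FALSE)
  vals <- as.numeric(unlist(strsplit(trimws(ln[-1]), "\\s+")))
  vals <- vals[!is.na(vals)]
  n <- (1 + sqrt(1 + 8 * length(vals))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("distance file does not hold R(R-1)/2 values")
  structure(list(label = label, r = vals, n_residues = as.integer(round(n))),
            class = "refdist")
}

#' Write a reference distance set as plain text
#' @param ref a `"refdist"`.
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  writeLines(c(paste0("# ", ref$label, " Calpha-Calpha distances (nm), R = ",
                      ref$n_residues),
               paste(format(ref$r, digits = 12), collapse = " ")), path)
  invisible(path)
}

#' Distance RMSD of a conformation against a reference
#'
#' @param ca_coords R x 3 matrix of Calpha coordinates in nm, or a
#'   precomputed distance vector of length R(R-1)/2 (nm).
#' @param ref a `"refdist"`.
#' @return DRMSD in Angstrom.
#' @export
drmsd <- function(ca_coords, ref) {
  d <- if (is.matrix(ca_coords)) {
    if (nrow(ca_coords) != ref$n_residues)
      stop("conformation has ", nrow(ca_coords), " residues, reference '",
           ref$label, "' has ", ref$n_residues)
    .ca_pair_distances(ca_coords)
  } else {
    if (length(ca_coords) != length(ref$r))
      stop("distance vector length mismatch")
    as.numeric(ca_coords)
  }
  10 * sqrt(mean((d - ref$r)^2))   # nm -> Angstrom
}

# Calpha coordinates of peptide i in frame f, made whole.
.ca_coords <- function(traj, frame, i) {
  sys <- traj$system
  idx <- .pep_idx(sys, i)
  xyz <- .make_whole(traj$coords[idx, , frame], traj$box[[frame]])
  xyz[sys$atoms$name[idx] == "CA", , drop = FALSE]
}

#' Per-peptide DRMSD series and window histograms
#'
#' @param traj a `"traj"`.
#' @param refs list of `"refdist"` objects (named or labelled).
#' @param window_ns trailing-window length in ns (histogram window; the
#'   series covers all frames).
#' @param bin histogram bin width in Angstrom.
#' @param peptides peptide subset (default all) — used e.g. to restrict to
#'   peptides in contact with the surface.
#' @return named list per reference, each with `series` (data.frame time,
#'   peptide, drmsd in Angstrom) and `hist` (data.frame mid, density; the
#'   histogram integrates to 1 over the window).
#' @export
drmsd_histograms <- function(traj, refs, window_ns = 100, bin = 0.1,
                             peptides = NULL) {
  if (inherits(refs, "refdist")) refs <- list(refs)
  labels <- vapply(seq_along(refs), function(k) {
    nm <- names(refs)[k]
    if (!is.null(nm) && nzchar(nm)) nm else refs[[k]]$label
  }, character(1))
  if (is.null(peptides)) peptides <- seq_len(traj$system$n_peptides)
  wf <- suppressWarnings(.window_frames(traj, window_ns))
  out <- list()
  for (k in seq_along(refs)) {
    ref <- refs[[k]]
    grid <- expand.grid(frame = seq_len(n_frames(traj)), peptide = peptides)
    vals <- mapply(function(f, i) drmsd(.ca_coords(traj, f, i), ref),
                   grid$frame, grid$peptide)
    series <- data.frame(time = traj$times[grid$frame],
                         peptide = grid$peptide, drmsd = vals)
    wvals <- vals[grid$frame %in% wf]
    brk <- seq(0, max(wvals) + bin, by = bin)
    h <- hist(wvals, breaks = brk, plot = FALSE)
    out[[labels[k]]] <- list(series = series,
                             hist = data.frame(mid = h$mids,
                                               density = h$density),
                             bin = bin)
  }
  out
}

#' Torsion (dihedral) angle of four points
#'
#' Standard four-atom torsion: the signed angle between the planes
#' (p1,p2,p3) and (p2,p3,p4), in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

# Backbone (phi, psi) pairs of peptide i in frame f for interior residues
# (both angles defined): phi_r needs C(r-1), psi_r needs N(r+1).
.phi_psi <- function(traj, frame, i) {
  sys <- traj$system
  idx <- .pep_idx(sys, i)
  at <- sys$atoms[idx, ]
  xyz <- .make_whole(traj$coords[idx, , frame], traj$box[[frame]])
  pick <- function(r, nm) {
    w <- which(at$resid == r & at$name == nm)
    if (length(w) != 1L)
      stop("missing backbone atom ", nm, " in residue ", r, " of peptide ", i)
    xyz[w, ]
  }
  R <- sys$n_residues
  if (R < 3L) return(NULL)
  t(vapply(2:(R - 1L), function(r) {
    c(phi = torsion_angle(pick(r - 1L, "C"), pick(r, "N"),
                          pick(r, "CA"), pick(r, "C")),
      psi = torsion_angle(pick(r, "N"), pick(r, "CA"),
                          pick(r, "C"), pick(r + 1L, "N")),
      residue = r)
  }, numeric(3)))
}

#' Ramachandran density over a trailing window
#'
#' Pools backbone (phi, psi) pairs of interior residues over all peptides
#' and window frames into a 2D histogram on (-180, 180] x (-180, 180].
#' Quadrant occupancies are reported alongside: the upper-left quadrant
#' (phi < 0, psi > 0) holds beta-strand conformations, the lower-left
#' (phi < 0, psi < 0) alpha-helical ones.
#'
#' @param traj a `"traj"`.
#' @param window_ns trailing-window length in ns.
#' @param bin bin width in degrees (must divide 360).
#' @param residues residue-position filter (default all interior residues).
#' @return object of class `"ramachandran"`: `density` (matrix, rows phi
#'   bins, cols psi bins, sums to 1), `breaks`, `quadrants` (named numeric:
#'   upper_left, lower_left, upper_right, lower_right), `angles`
#'   (data.frame time, peptide, residue, phi, psi).
#' @export
ramachandran <- function(traj, window_ns = 100, bin = 5, residues = NULL) {
  stopifnot(360 %% bin == 0)
  wf <- suppressWarnings(.window_frames(traj, window_ns))
  rows <- list()
  for (f in wf) for (i in seq_len(traj$system$n_peptides)) {
    pp <- .phi_psi(traj, f, i)
    if (is.null(pp)) next
    rows[[length(rows) + 1L]] <-
      data.frame(time = traj$times[f], peptide = i, residue = pp[, "residue"],
                 phi = pp[, "phi"], psi = pp[, "psi"])
  }
  ang <- do.call(rbind, rows)
  if (!is.null(residues)) ang <- ang[ang$residue %in% residues, ]
  if (is.null(ang) || nrow(ang) == 0L) stop("no dihedral angles available")
  brk <- seq(-180, 180, by = bin)
  cut2 <- function(x) pmin(pmax(ceiling((x + 180) / bin), 1L), length(brk) - 1L)
  dens <- matrix(0, length(brk) - 1L, length(brk) - 1L)
  ij <- cbind(cut2(ang$phi), cut2(ang$psi))
  for (r in seq_len(nrow(ij))) dens[ij[r, 1], ij[r, 2]] <-
    dens[ij[r, 1], ij[r, 2]] + 1
  dens <- dens / sum(dens)
  quad <- c(upper_left = mean(ang$phi < 0 & ang$psi > 0),
            lower_left = mean(ang$phi < 0 & ang$psi <= 0),
            upper_right = mean(ang$phi >= 0 & ang$psi > 0),
            lower_right = mean(ang$phi >= 0 & ang$psi <= 0))
  structure(list(density = dens, breaks = brk, quadrants = quad,
                 angles = ang, bin = bin),
            class = "ramachandran")
}

#' @export
print.ramachandran <- function(x, ...) {
  cat("Ramachandran density (", nrow(x$angles), " angle pairs, ", x$bin,
      " deg bins). Quadrant occupancy:\n", sep = "")
  print(round(x$quadrants, 3))
  invisible(x)
}
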