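#' @importFrom stats rnorm runif setNames aggregate
#' @importFrom utils head tail write.csv read.csv
NULL

# Atomic masses (amu) used when a file carries no mass information.
.ELEMENT_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, AU = 196.967)

# Residue names recognised as peptide residues (three-letter codes).
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Construct a simulation box
#'
#' Boxes are orthorhombic: three edge lengths in nm plus a per-axis
#' periodicity flag. Surface systems are conventionally periodic in x and y
#' only (the slab plus vacuum makes z-wrapping meaningless for
#' peptide--surface distances); bulk-solution systems are periodic in all
#' three axes.
#'
#' @param lengths numeric length-3, box edge lengths in nm (all > 0).
#' @param periodic logical length-3, per-axis periodicity flags.
#' @return an object of class `"box"`.
#' @export
box_spec <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) == 3L, length(periodic) == 3L)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("box edge lengths must be strictly positive")
  structure(list(lengths = lengths, periodic = as.logical(periodic)),
            class = "box")
}

#' Minimum-image distance between two points
#'
#' Returns the smallest |a - b| over periodic images in the axes flagged
#' periodic, and the plain Euclidean separation in non-periodic axes.
#'
#' @param a,b numeric length-3 coordinates in nm.
#' @param box a [box_spec()] object.
#' @return distance in nm.
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- as.numeric(a) - as.numeric(b)
  w <- box$periodic
  if (any(w)) d[w] <- d[w] - box$lengths[w] * round(d[w] / box$lengths[w])
  sqrt(sum(d * d))
}

# Minimum-image displacement applied column-wise to an n x 3 matrix.
.min_image <- function(d, box) {
  for (k in which(box$periodic)) {
    L <- box$lengths[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  d
}

# Cross squared-distance matrix between coordinate sets x1 (n1 x 3) and
# x2 (n2 x 3) under the minimum-image convention.
.cross_dist2 <- function(x1, x2, box) {
  d2 <- matrix(0, nrow(x1), nrow(x2))
  for (k in 1:3) {
    dk <- outer(x1[, k], x2[, k], "-")
    if (box$periodic[k]) {
      L <- box$lengths[k]
      dk <- dk - L * round(dk / L)
    }
    d2 <- d2 + dk * dk
  }
  d2
}

.infer_element <- function(name, elesy = NULL) {
  if (!is.null(elesy) && !is.na(elesy) && nzchar(trimws(elesy)))
    return(toupper(trimws(elesy)))
  nm <- sub("^[0-9']+", "", toupper(name))   # PDB-style leading digits (e.g. 1HB)
  if (grepl("^AU", nm)) return("AU")
  first <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  if (identical(first, "")) stop("cannot infer element from atom name '", name, "'")
  first
}

.element_mass <- function(el) {
  m <- .ELEMENT_MASS[toupper(el)]
  m[is.na(m)] <- 12.011   # unknown pseudo-atoms default to carbon mass
  unname(m)
}

#' Assemble a molecular system from an atom table
#'
#' The central container every analysis indexes into: atoms grouped into
#' residues grouped into peptide copies, plus (optionally) a gold slab.
#' All peptide copies must share the same residue sequence and atom count
#' (homo-oligomer assumption).
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid` (residue position 1..R within its peptide), `peptide`
#'   (1..Nmol; `NA` for non-peptide atoms such as slab gold), and optionally
#'   `mass`, `chain`.
#' @param surface optional [surface_model()] describing a slab.
#' @return object of class `"molsys"` with elements `atoms` (augmented with
#'   `mass` and logical `heavy`), `n_peptides`, `n_residues`,
#'   `residue_names`, `surface`.
#' @export
molecular_system <- function(atoms, surface = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "resname", "resid", "peptide") %in% names(atoms)))
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  if (is.null(atoms$chain)) atoms$chain <- NA_character_
  atoms$heavy <- !(toupper(atoms$element) %in% c("H", "D"))
  pep <- atoms$peptide
  ids <- sort(unique(pep[!is.na(pep)]))
  if (length(ids) == 0L) stop("no peptide atoms found")
  if (!identical(ids, seq_along(ids))) stop("peptide indices must be 1..Nmol")
  sig <- vapply(ids, function(i) {
    a <- atoms[!is.na(pep) & pep == i, ]
    paste(paste(a$resid, a$resname, a$name, sep = ":"), collapse = "|")
  }, character(1))
  if (length(unique(sig)) != 1L) {
    bad <- ids[sig != sig[1]][1]
    stop("peptide ", bad, " does not match peptide 1 in residue/atom layout ",
         "(homo-oligomer assumption violated)")
  }
  first <- atoms[!is.na(pep) & pep == 1L, ]
  rn <- first$resname[!duplicated(first$resid)]
  structure(list(atoms = atoms,
                 n_peptides = length(ids),
                 n_residues = max(first$resid),
                 residue_names = rn,
                 surface = surface),
            class = "molsys")
}

#' @export
print.molsys <- function(x, ...) {
  cat("Molecular system: ", x$n_peptides, " peptide(s) x ", x$n_residues,
      " residues (", paste(x$residue_names, collapse = "-"), "), ",
      nrow(x$atoms), " atoms",
      if (!is.null(x$surface)) ", with surface slab" else "", "\n", sep = "")
  invisible(x)
}

# Peptide identification: by chain tag when present and informative, else by
# residue-number restarts (GRO files often lack chain IDs).
.assign_peptides <- function(resname, resno, chain) {
  is_pep <- toupper(resname) %in% .AA3
  pep <- rep(NA_integer_, length(resname))
  if (!any(is_pep)) return(pep)
  ch <- chain[is_pep]
  if (!all(is.na(ch)) && length(unique(ch[!is.na(ch)])) > 1L) {
    pep[is_pep] <- as.integer(factor(ch, levels = unique(ch)))
  } else {
    rn <- resno[is_pep]
    newmol <- c(TRUE, diff(rn) < 0)
    pep[is_pep] <- cumsum(newmol)
  }
  pep
}

# Renumber residues 1..R within each peptide.
.local_resid <- function(resno, pep) {
  out <- rep(NA_integer_, length(resno))
  for (i in unique(pep[!is.na(pep)])) {
    sel <- which(!is.na(pep) & pep == i)
    out[sel] <- as.integer(factor(resno[sel], levels = unique(resno[sel])))
  }
  out
}

#' Load a molecular system from a PDB or GRO file
#'
#' Peptide copies are identified by chain/segment ID when present, otherwise
#' by residue-numbering restarts. Gold atoms (element Au) are excluded from
#' the peptide set but retained: when present, the top atomic layer is
#' located and a [surface_model()] attached. Coordinates are converted to nm
#' (PDB files are in Angstrom).
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @return list with elements `system` (a `"molsys"`), `xyz`
#'   (n_atoms x 3 matrix, nm) and `box` (a `"box"`, or `NULL` if the file
#'   declares none).
#' @export
load_system <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
                   gro = .read_gro(path),
                   pdb = .read_pdb_topology(path),
                   stop("unsupported topology format '.", ext, "' (use PDB or GRO)"))
  at <- parsed$atoms
  at$element <- mapply(.infer_element, at$name, at$elesy)
  is_au <- at$element == "AU"
  at$peptide <- .assign_peptides(at$resname, at$resno, at$chain)
  at$peptide[is_au] <- NA_integer_
  at$resid <- .local_resid(at$resno, at$peptide)
  at$resid[is.na(at$peptide)] <- NA_integer_
  surface <- NULL
  if (any(is_au)) {
    zs <- parsed$xyz[is_au, 3]
    top <- .top_layer_z(zs)
    xs <- parsed$xyz[is_au, 1]; ys <- parsed$xyz[is_au, 2]
    surface <- surface_model(lx = diff(range(xs)), ly = diff(range(ys)),
                             top_z = top, layers = .count_layers(zs))
    if (!is.null(parsed$box)) {
      surface$lx <- parsed$box$lengths[1]
      surface$ly <- parsed$box$lengths[2]
    }
  }
  atoms <- data.frame(name = at$name, element = at$element,
                      resname = toupper(at$resname), resid = at$resid,
                      peptide = at$peptide, chain = at$chain,
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, surface = surface)
  box <- parsed$box
  if (!is.null(box) && !is.null(surface)) box$periodic <- c(TRUE, TRUE, FALSE)
  list(system = sys, xyz = parsed$xyz, box = box)
}

.read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) / 10   # Angstrom -> nm
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr)) {
    L <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33))) / 10
    if (all(is.finite(L)) && all(L > 0)) box <- box_spec(L)
  }
  list(atoms = data.frame(name = a$elety, resname = a$resid, resno = a$resno,
                          chain = a$chain, elesy = a$elesy,
                          stringsAsFactors = FALSE),
       xyz = xyz, box = box)
}

# GRO fixed-width reader (no installed R package parses GRO).
.read_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 3L) stop("unparseable GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n) || length(ln) < n + 3L) stop("unparseable GRO file: ", path)
  rec <- ln[3:(2 + n)]
  resno <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28))
  y <- as.numeric(substr(rec, 29, 36))
  z <- as.numeric(substr(rec, 37, 44))
  if (anyNA(c(x, y, z))) stop("unparseable coordinates in GRO file: ", path)
  bv <- suppressWarnings(as.numeric(strsplit(trimws(ln[n + 3L]), "\\s+")[[1]]))
  box <- if (length(bv) >= 3 && all(bv[1:3] > 0)) box_spec(bv[1:3]) else NULL
  list(atoms = data.frame(name = name, resname = resname, resno = resno,
                          chain = NA_character_, elesy = NA_character_,
                          stringsAsFactors = FALSE),
       xyz = cbind(x, y, z), box = box)
}

#' Load a trajectory for a previously loaded system
#'
#' Supported formats: multi-model PDB (Angstrom, converted to nm), GRO
#' (single frame), and binary DCD via [bio3d::read.dcd()]. Frame times are
#' taken as `(frame - 1) * stride_ps` unless the format carries times.
#'
#' @param system a `"molsys"` from [load_system()].
#' @param path trajectory file path.
#' @param stride_ps time between stored frames, in ps.
#' @param box fallback [box_spec()] used when frames carry no box.
#' @return object of class `"traj"`: the bound system, a
#'   n_atoms x 3 x n_frames coordinate array (nm), frame times (ps) and a
#'   3 x n_frames matrix of box edges.
#' @export
load_trajectory <- function(system, path, stride_ps = 1, box = NULL) {
  ext <- tolower(tools::file_ext(path))
  na <- nrow(system$atoms)
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz / 10
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    if (ncol(xyz) != 3L * na)
      stop("atom count mismatch: trajectory has ", ncol(xyz) / 3,
           " atoms, system has ", na)
    coords <- array(0, dim = c(na, 3L, nf))
    for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    parsed_box <- .read_pdb_topology(path)$box
  } else if (ext == "gro") {
    g <- .read_gro(path)
    if (nrow(g$xyz) != na) stop("atom count mismatch")
    coords <- array(g$xyz, dim = c(na, 3L, 1L))
    parsed_box <- g$box
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10
    if (ncol(xyz) != 3L * na) stop("atom count mismatch")
    nf <- nrow(xyz)
    coords <- array(0, dim = c(na, 3L, nf))
    for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    parsed_box <- NULL
  } else {
    stop("unsupported trajectory format '.", ext,
         "' (use multi-model PDB, GRO or DCD)")
  }
  if (is.null(box)) box <- parsed_box
  if (is.null(box)) stop("no box in trajectory; supply `box`")
  if (!is.null(system$surface)) box$periodic <- c(TRUE, TRUE, FALSE)
  nf <- dim(coords)[3]
  trajectory(system, coords, times = (seq_len(nf) - 1) * stride_ps, box = box)
}

#' Construct a trajectory object
#'
#' @param system a `"molsys"`.
#' @param coords n_atoms x 3 x n_frames array, nm.
#' @param times frame times in ps, strictly increasing.
#' @param box a [box_spec()] (shared by all frames) or a list of one per frame.
#' @return object of class `"traj"`.
#' @export
trajectory <- function(system, coords, times, box) {
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (nf == 0L) stop("no frames")
  if (dim(coords)[1] != nrow(system$atoms))
    stop("coordinate array length (", dim(coords)[1],
         ") does not match system atom count (", nrow(system$atoms), ")")
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (inherits(box, "box")) box <- rep(list(box), nf)
  stopifnot(length(box) == nf)
  structure(list(system = system, coords = coords, times = as.numeric(times),
                 box = box),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat("Trajectory: ", n_frames(x), " frames, ",
      x$times[1], "..", x$times[n_frames(x)], " ps; ", sep = "")
  print(x$system)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `"traj"`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#' @param traj a `"traj"`.
#' @param i frame index.
#' @return list with `time` (ps), `xyz` (n x 3, nm), `box`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(time = traj$times[i], xyz = traj$coords[, , i, drop = TRUE],
       box = traj$box[[i]])
}

# Frame indices of a trailing analysis window. The window defaults to the
# trailing 100 ns; when the trajectory is shorter it falls back to the
# trailing 20% of frames with a warning so that short synthetic runs work.
.window_frames <- function(traj, window_ns = 100) {
  tt <- traj$times
  span <- tt[length(tt)] - tt[1]
  w_ps <- window_ns * 1000
  if (span + 1e-9 < w_ps) {
    warning("trajectory (", span / 1000, " ns) shorter than window (",
            window_ns, " ns); using trailing 20% of frames instead",
            call. = FALSE)
    k <- max(1L, ceiling(0.2 * length(tt)))
    return(seq(length(tt) - k + 1L, length(tt)))
  }
  which(tt >= tt[length(tt)] - w_ps)
}

# Row indices of atoms of peptide i (optionally heavy only / one residue).
.pep_idx <- function(system, i, heavy_only = FALSE, resid = NULL) {
  a <- system$atoms
  sel <- !is.na(a$peptide) & a$peptide == i
  if (heavy_only) sel <- sel & a$heavy
  if (!is.null(resid)) sel <- sel & a$resid == resid
  which(sel)
}

# Make a peptide whole across periodic boundaries by chaining each atom to
# its minimum image relative to the previous atom (atoms are stored in
# backbone order, so consecutive atoms are near-bonded).
.make_whole <- function(xyz, box) {
  if (!any(box$periodic)) return(xyz)
  n <- nrow(xyz)
  if (n < 2L) return(xyz)
  for (k in which(box$periodic)) {
    L <- box$lengths[k]
    d <- diff(xyz[, k])
    shift <- cumsum(-L * round(d / L))
    xyz[2:n, k] <- xyz[2:n, k] + shift
  }
  xyz
}

#' Write a system + coordinates as a GRO file
#'
#' @param system a `"molsys"`.
#' @param xyz n x 3 matrix in nm.
#' @param box a [box_spec()].
#' @param path output path.
#' @param title title line.
#' @export
write_gro <- function(system, xyz, box, path, title = "surfagg system") {
  a <- system$atoms
  n <- nrow(a)
  resno <- .global_resno(system)
  rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                 resno %% 100000L, substr(a$resname, 1, 5),
                 substr(a$name, 1, 5), seq_len(n) %% 100000L,
                 xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(title, sprintf("%5d", n), rec,
               sprintf("%10.5f%10.5f%10.5f", box$lengths[1], box$lengths[2],
                       box$lengths[3])), path)
  invisible(path)
}

# Residue numbering for output files: restarts at 1 for every peptide (so
# chain-less formats like GRO still reveal the peptide boundaries), slab
# atoms numbered after the last peptide residue.
.global_resno <- function(system) {
  a <- system$atoms
  r <- a$resid
  slab <- is.na(a$peptide)
  if (any(slab)) r[slab] <- max(0L, r[!slab]) + 1L
  r
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written in Angstrom (PDB convention); a CRYST1 record
#' carries the box of the first frame.
#'
#' @param traj a `"traj"`.
#' @param path output path.
#' @export
write_pdb_trajectory <- function(traj, path) {
  sys <- traj$system
  a <- sys$atoms
  resno <- .global_resno(sys)
  chain <- ifelse(is.na(a$peptide), "Z",
                  strsplit(paste(LETTERS, collapse = ""), "")[[1]][
                    pmin(a$peptide, 26L)])
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box[[1]]$lengths * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     b[1], b[2], b[3]), con)
  el <- ifelse(a$element == "AU", "AU", substr(a$element, 1, 1))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f] * 10
    nm4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
    writeLines(sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(a)) %% 100000L, nm4,
                       substr(a$resname, 1, 4), chain, resno %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3], el), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a labelled residue-by-residue matrix as CSV
#'
#' @param m R x R matrix with residue labels as dimnames.
#' @param path output path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# One-letter + position residue labels, e.g. K16..E22 for KLVFFAE numbered
# from 16 (the amyloid-beta fragment convention).
.ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

#' Residue labels of a system
#'
#' @param system a `"molsys"`.
#' @param first_number sequence number of the first residue (16 for the
#'   amyloid-beta 16--22 fragment).
#' @return character vector of length R, e.g. `c("K16", ..., "E22")`.
#' @export
residue_labels <- function(system, first_number = 16L) {
  one <- .ONE[system$residue_names]
  one[is.na(one)] <- "X"
  paste0(one, seq_along(one) + first_number - 1L)
}
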