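# Intermolecular residue-residue contact maps and backbone hydrogen-bond
# maps. Contacts use the same heavy-atom < cutoff criterion as the oligomer
# clustering; intra-peptide contacts are excluded throughout.

#' Intermolecular residue-residue contact map
#'
#' Entry (a, b) is the fraction of (window frame, peptide pair) combinations
#' in which any heavy atom of residue a of one peptide lies strictly within
#' `cutoff` of any heavy atom of residue b of the other; evidence from both
#' orientations ((i.a, j.b) and (i.b, j.a)) is pooled, so the map is
#' symmetric. `mode = "count"` returns mean contact counts per frame
#' instead of frequencies.
#'
#' @param traj a `"traj"`.
#' @param window_ns trailing-window length in ns.
#' @param cutoff heavy-atom contact cutoff in nm (strict inequality).
#' @param mode `"frequency"` (default, entries in `[0, 1]`) or `"count"`.
#' @return object of class `"contact_map"`: `map` (R x R labelled matrix),
#'   `window`, `mode`, `cutoff`.
#' @export
residue_contact_map <- function(traj, window_ns = 100, cutoff = 0.4,
                                mode = c("frequency", "count")) {
  mode <- match.arg(mode)
  sys <- traj$system
  n <- sys$n_peptides
  R <- sys$n_residues
  wf <- suppressWarnings(.window_frames(traj, window_ns))
  labs <- residue_labels(sys)
  acc <- matrix(0, R, R, dimnames = list(labs, labs))
  # heavy-atom indices per (peptide, residue)
  hidx <- lapply(seq_len(n), function(i)
    lapply(seq_len(R), function(r) .pep_idx(sys, i, heavy_only = TRUE,
                                            resid = r)))
  npair <- n * (n - 1) / 2
  if (npair == 0) stop("need at least two peptides for a contact map")
  for (f in wf) {
    fr <- get_frame(traj, f)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      hit <- matrix(FALSE, R, R)
      for (a in seq_len(R)) for (b in seq_len(R)) {
        xa <- fr$xyz[hidx[[i]][[a]], , drop = FALSE]
        xb <- fr$xyz[hidx[[j]][[b]], , drop = FALSE]
        if (min(.cross_dist2(xa, xb, fr$box)) < cutoff^2) hit[a, b] <- TRUE
      }
      sym <- hit | t(hit)    # orientation-pooled evidence
      acc <- acc + sym
    }
  }
  map <- acc / (length(wf) * npair)
  if (mode == "count") map <- acc / length(wf)
  structure(list(map = map,
                 window = c(start = traj$times[wf[1]],
                            end = traj$times[wf[length(wf)]]),
                 mode = mode, cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Residue contact map (", x$mode, ", cutoff ", x$cutoff, " nm):\n",
      sep = "")
  print(round(x$map, 3))
  invisible(x)
}

# Donor (N, H) and acceptor (O) atom indices per (peptide, residue).
# Backbone only by default; side-chain donors/acceptors of K (NZ/HZ*) and
# E (OE*) are included on request when present in the topology.
.hbond_sites <- function(sys, include_sidechains = FALSE) {
  a <- sys$atoms
  donors <- list(); acceptors <- list()
  for (i in seq_len(sys$n_peptides)) {
    for (r in seq_len(sys$n_residues)) {
      sel <- which(!is.na(a$peptide) & a$peptide == i & a$resid == r)
      nm <- a$name[sel]
      dn <- sel[nm == "N"]; dh <- sel[nm %in% c("H", "HN", "H1")]
      if (length(dn) == 1L && length(dh) >= 1L)
        donors[[length(donors) + 1L]] <-
          list(peptide = i, resid = r, d = dn, h = dh[1])
      ac <- sel[nm == "O"]
      for (o in ac)
        acceptors[[length(acceptors) + 1L]] <-
          list(peptide = i, resid = r, a = o)
      if (include_sidechains) {
        sdn <- sel[nm == "NZ"]; sdh <- sel[grepl("^HZ", nm)]
        if (length(sdn) == 1L && length(sdh) >= 1L)
          donors[[length(donors) + 1L]] <-
            list(peptide = i, resid = r, d = sdn, h = sdh[1])
        for (o in sel[grepl("^OE", nm)])
          acceptors[[length(acceptors) + 1L]] <-
            list(peptide = i, resid = r, a = o)
      }
    }
  }
  list(donors = donors, acceptors = acceptors)
}

#' Interpeptide hydrogen-bond map
#'
#' A hydrogen bond is counted when the donor--acceptor heavy-atom distance
#' is at most `d_cut` and the hydrogen--donor--acceptor angle at most
#' `angle_cut` (geometric criterion in the convention of common MD analysis
#' tools). Entry (a, b) is the mean count per window frame of interpeptide
#' H-bonds between residue positions a and b, pooled over both
#' donor/acceptor orientations (symmetric map).
#'
#' @param traj a `"traj"` whose topology includes backbone amide hydrogens.
#' @param window_ns trailing-window length in ns.
#' @param d_cut donor--acceptor distance cutoff in nm.
#' @param angle_cut H--donor--acceptor angle cutoff in degrees.
#' @param include_sidechains also use Lys/Glu side-chain donors/acceptors
#'   when present.
#' @return object of class `"hbond_map"`: `map` (R x R labelled matrix of
#'   mean counts per frame), `window`, `criterion`.
#' @export
hydrogen_bond_map <- function(traj, window_ns = 100, d_cut = 0.35,
                              angle_cut = 30, include_sidechains = FALSE) {
  sys <- traj$system
  sites <- .hbond_sites(sys, include_sidechains)
  if (length(sites$donors) == 0L)
    stop("topology has no amide hydrogens; hydrogen positions are required ",
         "(re-run with a hydrogen-bearing topology or use the heavy-atom ",
         "contact map instead)")
  R <- sys$n_residues
  labs <- residue_labels(sys)
  wf <- suppressWarnings(.window_frames(traj, window_ns))
  acc <- matrix(0, R, R, dimnames = list(labs, labs))
  cosmin <- cos(angle_cut * pi / 180)
  for (f in wf) {
    fr <- get_frame(traj, f)
    for (dn in sites$donors) for (ac in sites$acceptors) {
      if (dn$peptide == ac$peptide) next
      xd <- fr$xyz[dn$d, ]; xa <- fr$xyz[ac$a, ]
      dda <- .min_image(matrix(xa - xd, 1), fr$box)[1, ]
      if (sqrt(sum(dda^2)) > d_cut) next
      xh <- fr$xyz[dn$h, ]
      dh <- .min_image(matrix(xh - xd, 1), fr$box)[1, ]
      ca <- sum(dh * dda) / sqrt(sum(dh^2) * sum(dda^2))
      if (ca >= cosmin) {
        acc[dn$resid, ac$resid] <- acc[dn$resid, ac$resid] + 0.5
        acc[ac$resid, dn$resid] <- acc[ac$resid, dn$resid] + 0.5
      }
    }
  }
  structure(list(map = acc / length(wf),
                 window = c(start = traj$times[wf[1]],
                            end = traj$times[wf[length(wf)]]),
                 criterion = list(d_cut = d_cut, angle_cut = angle_cut,
                                  convention = "H-donor-acceptor angle",
                                  sidechains = include_sidechains)),
            class = "hbond_map")
}

#' @export
print.hbond_map <- function(x, ...) {
  cat("Interpeptide hydrogen-bond map (mean bonds/frame, d <= ",
      x$criterion$d_cut, " nm, angle <= ", x$criterion$angle_cut, " deg):\n",
      sep = "")
  print(round(x$map, 3))
  invisible(x)
}
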