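# Gyration-tensor shape descriptors.
#
# The gyration tensor is the (mass-weighted) second-moment tensor of atomic
# positions about the centre of mass; its sorted eigenvalues describe
# aggregate shape. We report their square roots Gmax >= Gmid >= Gmin
# (principal radii, nm) so values are commensurate with molecular lengths;
# the raw eigenvalues (nm^2) are kept alongside. Linear monolayer aggregates
# show Gmin comparable to a single peptide's, compact solution aggregates
# do not.

# Unwrap a cluster across periodic boundaries: breadth-first over the
# peptide contact graph from the lowest-index member, shifting each newly
# reached peptide by whole box vectors so its closest heavy-atom pair to the
# already-placed neighbour realises the minimum image. Returns the shifted
# coordinates of the member peptides plus a flag for clusters that span a
# full periodic axis (which cannot be made whole consistently).
.unwrap_cluster <- function(traj, frame, members, cutoff = 0.4) {
  sys <- traj$system
  fr <- get_frame(traj, frame)
  box <- fr$box
  members <- sort(members)
  idx <- lapply(members, .pep_idx, system = sys)
  hidx <- lapply(members, .pep_idx, system = sys, heavy_only = TRUE)
  xyz <- lapply(idx, function(k) .make_whole(fr$xyz[k, , drop = FALSE], box))
  hx <- lapply(seq_along(members), function(m)
    xyz[[m]][match(hidx[[m]], idx[[m]]), , drop = FALSE])
  nm <- length(members)
  placed <- c(TRUE, rep(FALSE, nm - 1L))
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (nm < 2L) break
    for (m in seq_len(nm)[!placed]) {
      d2 <- .cross_dist2(hx[[cur]], hx[[m]], box)
      if (min(d2) < cutoff^2) {
        # shift peptide m by the image vector of its closest contact pair
        w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
        pa <- hx[[cur]][w[1], ]; pb <- hx[[m]][w[2], ]
        shift <- numeric(3)
        for (k in which(box$periodic)) {
          L <- box$lengths[k]
          shift[k] <- -L * round((pb[k] - pa[k]) / L)
        }
        xyz[[m]] <- sweep(xyz[[m]], 2, shift, "+")
        hx[[m]] <- sweep(hx[[m]], 2, shift, "+")
        placed[m] <- TRUE
        queue <- c(queue, m)
      }
    }
  }
  # peptides not reachable through contacts keep their min-image position
  # relative to the anchor's centre of mass
  if (any(!placed)) {
    anchor_com <- colMeans(xyz[[1]])
    for (m in seq_len(nm)[!placed]) {
      com <- colMeans(xyz[[m]])
      shift <- numeric(3)
      for (k in which(box$periodic)) {
        L <- box$lengths[k]
        shift[k] <- -L * round((com[k] - anchor_com[k]) / L)
      }
      xyz[[m]] <- sweep(xyz[[m]], 2, shift, "+")
    }
  }
  all_xyz <- do.call(rbind, xyz)
  spans <- vapply(1:3, function(k) diff(range(all_xyz[, k])), numeric(1))
  flagged <- any(box$periodic & spans >= box$lengths - 1e-9)
  list(xyz = all_xyz, atom_idx = unlist(idx), flagged = flagged)
}

# Principal radii of a point set (optionally mass-weighted).
.gyration <- function(xyz, mass = NULL) {
  if (is.null(mass)) mass <- rep(1, nrow(xyz))
  w <- mass / sum(mass)
  com <- colSums(xyz * w)
  d <- sweep(xyz, 2, com)
  S <- crossprod(d * w, d)           # sum_i w_i d_i d_i^T
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(eigenvalues = ev, radii = sqrt(ev), rg = sqrt(sum(ev)))
}

#' Gyration-tensor spectrum of an oligomer
#'
#' The cluster is made whole across periodic boundaries (minimum-image
#' chaining from the lowest-index member over the contact graph) before the
#' tensor is computed. Clusters spanning a full periodic axis cannot be
#' unwrapped consistently and are returned flagged.
#'
#' @param traj a `"traj"`.
#' @param frame frame index.
#' @param members integer vector of peptide indices forming the cluster.
#' @param mass_weighted mass-weight the tensor (default) or treat all atoms
#'   equally.
#' @param cutoff contact cutoff (nm) used for unwrap chaining.
#' @return object of class `"gyration_result"`: `gmax`, `gmid`, `gmin`
#'   (principal radii, nm), `rg` (nm), `eigenvalues` (nm^2), `members`,
#'   `time`, `flagged`.
#' @export
gyration_spectrum <- function(traj, frame, members, mass_weighted = TRUE,
                              cutoff = 0.4) {
  if (length(members) < 1L) stop("members must be non-empty")
  uw <- .unwrap_cluster(traj, frame, members, cutoff)
  mass <- if (mass_weighted) traj$system$atoms$mass[uw$atom_idx] else NULL
  g <- .gyration(uw$xyz, mass)
  structure(list(gmax = g$radii[1], gmid = g$radii[2], gmin = g$radii[3],
                 rg = g$rg, eigenvalues = g$eigenvalues,
                 members = sort(members), time = traj$times[frame],
                 flagged = uw$flagged),
            class = "gyration_result")
}

#' @export
print.gyration_result <- function(x, ...) {
  cat(sprintf("Gyration spectrum (t = %g ps, %d peptide(s)%s): Gmax %.3f  Gmid %.3f  Gmin %.3f  Rg %.3f nm\n",
              x$time, length(x$members), if (x$flagged) ", FLAGGED" else "",
              x$gmax, x$gmid, x$gmin, x$rg))
  invisible(x)
}

#' Per-frame gyration spectra of all oligomers
#'
#' @param traj a `"traj"`.
#' @param cutoff contact cutoff in nm.
#' @param frames frame indices (default all).
#' @param mass_weighted see [gyration_spectrum()].
#' @return data.frame: time, cluster (rank in frame), size, gmax, gmid,
#'   gmin, rg, flagged.
#' @export
oligomer_gyration_series <- function(traj, cutoff = 0.4, frames = NULL,
                                     mass_weighted = TRUE) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  rows <- list()
  for (f in frames) {
    part <- partition_frame(traj, f, cutoff)
    for (ci in seq_along(part$clusters)) {
      g <- gyration_spectrum(traj, f, part$clusters[[ci]], mass_weighted,
                             cutoff)
      rows[[length(rows) + 1L]] <-
        data.frame(time = g$time, cluster = ci,
                   size = length(part$clusters[[ci]]),
                   gmax = g$gmax, gmid = g$gmid, gmin = g$gmin, rg = g$rg,
                   flagged = g$flagged)
    }
  }
  do.call(rbind, rows)
}

#' Window-averaged single-peptide gyration spectra
#'
#' The monolayer/ribbon comparisons are made against individual molecules:
#' this returns each peptide's principal radii averaged over the trailing
#' window, treating every peptide on its own (whatever cluster it is in).
#'
#' @param traj a `"traj"`.
#' @param window_ns trailing-window length in ns.
#' @param mass_weighted see [gyration_spectrum()].
#' @return data.frame: peptide, gmax, gmid, gmin, rg (window means, nm).
#' @export
single_peptide_spectrum <- function(traj, window_ns = 100,
                                    mass_weighted = TRUE) {
  fr <- suppressWarnings(.window_frames(traj, window_ns))
  sys <- traj$system
  out <- lapply(seq_len(sys$n_peptides), function(i) {
    idx <- .pep_idx(sys, i)
    mass <- if (mass_weighted) sys$atoms$mass[idx] else NULL
    vals <- vapply(fr, function(f) {
      xyz <- .make_whole(traj$coords[idx, , f], traj$box[[f]])
      g <- .gyration(xyz, mass)
      c(g$radii, g$rg)
    }, numeric(4))
    m <- rowMeans(vals)
    data.frame(peptide = i, gmax = m[1], gmid = m[2], gmin = m[3], rg = m[4])
  })
  do.call(rbind, out)
}
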