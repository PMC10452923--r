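# Oligomer detection by the heavy-atom contact criterion.
#
# Two peptides belong to the same cluster when any pair of heavy
# (non-hydrogen) atoms, one from each, is strictly closer than the cutoff
# (default 4 A = 0.4 nm) under the minimum-image convention; oligomers are
# the connected components of this contact graph (single linkage).

#' Are two peptides in heavy-atom contact?
#'
#' @param traj a `"traj"`.
#' @param frame frame index.
#' @param i,j peptide indices (1..Nmol), distinct.
#' @param cutoff contact cutoff in nm; the comparison is strict (`< cutoff`).
#' @return logical.
#' @export
peptide_contact <- function(traj, frame, i, j, cutoff = 0.4) {
  if (i == j) stop("peptide indices must differ (i = j = ", i, ")")
  fr <- get_frame(traj, frame)
  xi <- fr$xyz[.pep_idx(traj$system, i, heavy_only = TRUE), , drop = FALSE]
  xj <- fr$xyz[.pep_idx(traj$system, j, heavy_only = TRUE), , drop = FALSE]
  min(.cross_dist2(xi, xj, fr$box)) < cutoff^2
}

# Union-find over peptide indices.
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Contact-pair matrix (2 columns, i < j) for one frame.
.contact_pairs <- function(traj, frame, cutoff) {
  n <- traj$system$n_peptides
  fr <- get_frame(traj, frame)
  idx <- lapply(seq_len(n), .pep_idx, system = traj$system, heavy_only = TRUE)
  xs <- lapply(idx, function(k) fr$xyz[k, , drop = FALSE])
  pairs <- matrix(integer(0), ncol = 2)
  if (n < 2L) return(pairs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (min(.cross_dist2(xs[[i]], xs[[j]], fr$box)) < cutoff^2)
      pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

#' Partition one frame into oligomers
#'
#' Single-linkage clustering: connected components of the peptide contact
#' graph under the heavy-atom criterion. Components are sorted by size
#' (descending), ties broken by smallest member index.
#'
#' @inheritParams peptide_contact
#' @return object of class `"oligomer_partition"`: list with `time` (ps),
#'   `clusters` (list of integer vectors), `contacts` (2-column matrix of
#'   peptide pairs in contact).
#' @export
partition_frame <- function(traj, frame, cutoff = 0.4) {
  n <- traj$system$n_peptides
  pairs <- .contact_pairs(traj, frame, cutoff)
  parent <- seq_len(n)
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- .uf_find(parent, pairs[r, 1]); b <- .uf_find(parent, pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), .uf_find, parent = parent, integer(1))
  clusters <- unname(split(seq_len(n), root))
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, min, integer(1)))
  structure(list(time = traj$times[frame], clusters = clusters[ord],
                 contacts = pairs),
            class = "oligomer_partition")
}

#' @export
print.oligomer_partition <- function(x, ...) {
  cat("Oligomer partition at t =", x$time, "ps:",
      paste(vapply(x$clusters, function(cl) paste0("{", paste(cl, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Largest-oligomer size per frame
#'
#' @param traj a `"traj"`.
#' @param cutoff contact cutoff in nm.
#' @return data.frame with `time` (ps) and `size` (1..Nmol).
#' @export
largest_oligomer_series <- function(traj, cutoff = 0.4) {
  sizes <- vapply(seq_len(n_frames(traj)), function(f)
    max(lengths(partition_frame(traj, f, cutoff)$clusters)), integer(1))
  data.frame(time = traj$times, size = sizes)
}

#' Oligomer-size histogram over a trailing window
#'
#' Default weighting is peptide-centric: `P(s)` is the probability that a
#' randomly chosen peptide in a randomly chosen window frame belongs to a
#' cluster of size s, i.e. `P(s) = s * count(s) / (Nmol * n_frames)`.
#' `weighting = "cluster"` instead normalises raw cluster counts.
#'
#' @param traj a `"traj"`.
#' @param cutoff contact cutoff in nm.
#' @param window_ns trailing-window length in ns.
#' @param weighting `"peptide"` (default) or `"cluster"`.
#' @return object of class `"size_histogram"`: list with `p` (named vector
#'   over s = 1..Nmol), `window` (start/end ps), `weighting`.
#' @export
size_histogram <- function(traj, cutoff = 0.4, window_ns = 100,
                           weighting = c("peptide", "cluster")) {
  weighting <- match.arg(weighting)
  span_ns <- (traj$times[n_frames(traj)] - traj$times[1]) / 1000
  if (span_ns < window_ns)
    stop("trajectory spans ", span_ns, " ns, shorter than the ", window_ns,
         " ns window; pass an explicit smaller `window_ns`")
  fr <- .window_frames(traj, window_ns)
  n <- traj$system$n_peptides
  counts <- numeric(n)
  for (f in fr) {
    sz <- lengths(partition_frame(traj, f, cutoff)$clusters)
    for (s in sz) counts[s] <- counts[s] + 1
  }
  p <- if (weighting == "peptide") counts * seq_len(n) / (n * length(fr))
       else counts / sum(counts)
  structure(list(p = setNames(p, seq_len(n)),
                 window = c(start = traj$times[fr[1]],
                            end = traj$times[fr[length(fr)]]),
                 weighting = weighting),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat("Oligomer size histogram (", x$weighting, "-weighted, window ",
      x$window[1], "-", x$window[2], " ps):\n", sep = "")
  print(round(x$p, 4))
  invisible(x)
}
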