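# Fixtures are generated in code; nothing is read from disk.

# A "bead peptide" system: one heavy pseudo-atom per residue, n peptides,
# with explicit coordinates supplied per peptide as a list of R x 3
# matrices. Handy for planting exact distances.
bead_system <- function(coord_list, resnames = c("LYS", "LEU", "VAL", "PHE",
                                                 "PHE", "ALA", "GLU")) {
  n <- length(coord_list)
  R <- nrow(coord_list[[1]])
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(name = "CA", element = "C", resname = resnames[seq_len(R)],
               resid = seq_len(R), peptide = i, chain = "A",
               stringsAsFactors = FALSE)))
  sys <- molecular_system(atoms)
  xyz <- do.call(rbind, coord_list)
  list(system = sys, xyz = xyz)
}

bead_traj <- function(coord_list, box_len = c(20, 20, 20),
                      periodic = c(TRUE, TRUE, TRUE), times = 0, ...) {
  bs <- bead_system(coord_list, ...)
  nf <- length(times)
  coords <- array(rep(bs$xyz, nf), dim = c(nrow(bs$xyz), 3, nf))
  trajectory(bs$system, coords, times, box_spec(box_len, periodic))
}

# Independent minimum-image oracle: brute force over all 27 neighbour
# images in the periodic axes.
brute_min_image <- function(a, b, box) {
  shifts <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  best <- Inf
  for (r in seq_len(nrow(shifts))) {
    s <- as.numeric(shifts[r, ]) * box$lengths * box$periodic
    best <- min(best, sqrt(sum((a - (b + s))^2)))
  }
  best
}

# Independent single-linkage oracle: all-pairs heavy-atom distances with
# explicit loops, components via igraph.
oracle_partition <- function(traj, frame, cutoff = 0.4) {
  sys <- traj$system
  n <- sys$n_peptides
  fr <- get_frame(traj, frame)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- fr$xyz[which(sys$atoms$peptide %in% i & sys$atoms$heavy), , drop = FALSE]
    xj <- fr$xyz[which(sys$atoms$peptide %in% j & sys$atoms$heavy), , drop = FALSE]
    hit <- FALSE
    for (a in seq_len(nrow(xi))) {
      for (b in seq_len(nrow(xj))) {
        if (brute_min_image(xi[a, ], xj[b, ], fr$box) < cutoff) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    adj[i, j] <- adj[j, i] <- hit
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  unname(split(seq_len(n), igraph::components(g)$membership))
}

same_partition <- function(a, b) {
  norm <- function(p) {
    p <- lapply(p, function(x) sort(as.integer(x)))
    p[order(vapply(p, min, integer(1)))]
  }
  identical(norm(a), norm(b))
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
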