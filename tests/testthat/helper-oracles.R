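# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can stand as references.

bf_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

bf_contacts <- function(xyz, rec_idx, lig_idx, cutoff) {
  out <- NULL
  for (i in rec_idx) {
    for (j in lig_idx) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < cutoff) out <- rbind(out, c(i, j, d))
    }
  }
  out
}

# Signed dihedral angle (degrees) of four points, right-handed IUPAC
# convention (positive = clockwise rotation of the far bond viewed along
# the central bond), via the projection/atan2 formulation.
bf_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  cr <- c(b1[2] * v[3] - b1[3] * v[2],
          b1[3] * v[1] - b1[1] * v[3],
          b1[1] * v[2] - b1[2] * v[1])
  y <- sum(cr * w)
  atan2(y, x) * 180 / pi
}

# Random rigid transform (rotation + translation) applied to rows.
rigid_transform <- function(X, angle = 0.7, axis = c(1, 2, 2), shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(X %*% t(R), 2, -shift)
}

# Small two-chain test system: nr receptor + nl ligand atoms at seeded
# random coordinates.
random_system <- function(nr = 10, nl = 6, seed = 42, spread = 8) {
  set.seed(seed)
  pos <- matrix(runif((nr + nl) * 3, -spread, spread), ncol = 3)
  particle_system(pos, masses = 1,
                  role = c(rep("receptor", nr), rep("ligand", nl)),
                  charges = round(runif(nr + nl, -0.6, 0.6), 2))
}
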